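---
title: "Crop-based coarse-to-fine segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crop-based coarse-to-fine segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seg2seg)
```

## The problem

Biomedical images — microscopy fields, endoscopy frames, CT slices — are
routinely much larger than the input size a segmentation CNN can be trained
at on available memory. The common workaround, uniform downscaling, spends
the same pixel budget on salient and non-salient regions alike: small
objects shrink to a handful of pixels, boundaries become blocky, and recall
suffers first. This package implements the alternative of *cropping instead
of downscaling*: keep the network input small, but point it at the regions
that matter, at original resolution.

## The two-stage procedure

Let $I$ be an image of size $W \times H$ and $S$ the (shared) network input
size. Inference runs as follows.

1. **Rough stage.** Downscale $I$ uniformly to $S \times S$ and apply the
   rough segmenter $g_{\phi_1}$, giving a low-resolution binary mask
   $u$. This mask is only used to *locate* objects, so heavy downscaling is
   tolerable here.
2. **Crop regions.** Resize $u$ back to $W \times H$ (nearest-neighbour)
   and take its connected components. Each component yields its tight
   bounding box, which is then **squared** (both dimensions set to the
   larger one, top-left corner anchored), **padded** by $k = \lfloor S/8
   \rfloor$ pixels on each of the four sides so the crop retains context
   around the object, and **shifted** (size-preserving) to lie fully inside
   the image. Components whose tight box is narrower or shorter than 5
   pixels are discarded as segmentation noise.
3. **Fine stage.** Each box is cropped from $I$ *at original resolution*,
   rescaled to $S \times S$, and segmented by the fine segmenter
   $g_{\phi_2}$, a network of the same input size trained specifically on
   such crops. Its binarized output is rescaled back to the box size.
4. **Fusion.** The per-crop masks are placed back at their box positions
   and combined by pixel-wise logical OR (equivalently a per-pixel maximum
   of binary masks), giving the final $W \times H$ segmentation
   $y = \max_i (T_i \circ C_i^{-1})(Y_{f_i})$. OR fusion makes the result
   independent of crop order and of duplicated crops, and adding a crop can
   only add foreground — pixel recall is monotone in the crop set.

If the rough stage finds nothing (or only sub-threshold noise), inference
returns an all-background mask; the whole-image fallback described below is
a *training* rule and deliberately does not apply at inference.

Because each object is rescaled to a common size before the fine stage,
the fine network sees objects at unified scale, which is also why it
converges quickly in practice.

## Training the two networks

The rough network is trained on uniformly downscaled image/mask pairs —
it is exactly the baseline model, and doubles as the comparison point.

The fine network trains on **ground-truth crops**: crop regions are derived
from the connected components of the ground-truth mask through the same
square–pad–shift pipeline (no rough network involved). Per image and epoch:

* one crop region is chosen uniformly at random;
* the box is **jittered** — four independent integer offsets, each uniform
  on $[-16, +16]$ pixels, added to its left, top, width and height — so the
  network tolerates the imperfect boxes the rough stage produces at
  inference; a jittered dimension that would collapse is clamped to 1 pixel
  and the box is shifted back into bounds;
* image and mask are cropped with the *same* box and resized to
  $S \times S$ (masks always nearest-neighbour);
* if the image has no usable component, the whole image and mask are
  downscaled to $S \times S$ instead, preserving negative examples.

Both networks optimize soft Dice loss with Adam. After every epoch the mean
validation Dice is computed *at input resolution* (no upscaling, threshold
0.5) and the best-validation checkpoint is what training returns. Named
hyperparameter presets are available for the three reference regimes
(`train_preset("cells")`: batch 16, lr 5e-4, 100 epochs;
`"polyp"`: 8, 1e-3, 175; `"aorta"`: 8, 1e-3, 100).

For CT input, `ct_window()` implements the vascular preprocessing recipe:
clip to 200–500 HU, map linearly to $[-0.5, 0.5]$, subtract 0.1 (output
range $[-0.6, 0.4]$). The matching train-time geometric augmentation
(`augment()`) applies, with 50% probability, an affine transform of
±6.25% translation, ±10% scale and ±14° rotation about the image centre
(bilinear for the image, nearest for the mask), plus an independent 30%
horizontal flip.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `input_size` (S) | — | Shared network input size; crops and the downscaled image are S×S. |
| `padding` (k) | `floor(S/8)` | Context margin added on each side of a crop box, in full-resolution pixels. |
| `min_crop_px` | 5 | Components with a tighter bounding box are treated as rough-mask noise. |
| `connectivity` | 8 | Component connectivity; 8 merges diagonal touches (typical blob semantics), 4 available. |
| binarization threshold | 0.5 | Scores ≥ 0.5 are foreground, at both stages. |
| `max_jitter` | 16 px | Training-time box perturbation range. |

## Numerical choices

* **Coordinates** are 0-based with half-open extent, so `width`/`height`
  are exact pixel counts and crop slicing is unambiguous.
* **Padding** adds $k$ to *each* of the four sides (+2k per dimension).
  Padding is symmetric, so squaring and padding commute — a property the
  test suite checks on random boxes.
* **Squaring** anchors the top-left corner; the subsequent shift step
  corrects any out-of-bounds excursion. A box larger than the image (small
  images, large k) is clamped to the full image extent.
* **Noise filter space**: the <5 px rule is applied to the *tight*
  component box in original-image coordinates, before squaring and padding
  — after padding no box could ever be that small, so this is the only
  placement at which the rule can act.
* **Resizing** uses nearest-neighbour everywhere masks are involved, with
  the explicit index map `src = floor(dst * n_src / n_dst)`; this keeps
  binary masks binary and makes down-up roundtrips exactly reproducible on
  grid-aligned content (the property the exact-fit fixtures exploit).
  Results of any crop-based pipeline depend mildly on the resizing dialect;
  the map above is the package's fixed, documented choice, and bilinear
  resampling (half-pixel-centre convention) is available for images.
* **Box rescaling** between resolutions multiplies by the per-axis ratio
  and rounds half-to-even, with a 1-pixel floor on dimensions.
* **Jitter** draws integer offsets, matching pixel semantics; the four
  offsets are independent (position *and* size vary).
* **Scoring conventions**: empty prediction vs empty truth scores 1.0 on
  all metrics (a correctly empty image is a perfect prediction); a ratio
  with zero denominator against a non-empty counterpart scores 0.0.
  DSC and IoU always satisfy $DSC = 2\,IoU/(1+IoU)$.
* **Dice loss** uses an additive smoothing constant of 1 in numerator and
  denominator, which also defines the empty-empty case during training.

## The compact U-Net backend

The trainable segmenter is a small, self-contained encoder–decoder built
from 3×3 same-padding convolutions (ReLU), 2×2 max-pooling, nearest 2×
upsampling with skip concatenation, and a 1×1 sigmoid head; layer kernels
are compiled (im2col + BLAS) and the backward pass is exact, verified
against finite differences in the test suite. Depth (pooling steps) and
base width are configurable; `unet_init()` defaults to depth 3 with 16
base channels. Any model satisfying the two-line `segmenter()` contract —
S×S image in, S×S scores in [0, 1] out — can stand in for either stage, so
heavier architectures can be plugged in without touching the pipeline.

Training is fully seeded: weight init, shuffling, crop choice and jitter
all derive from `train_config()$seed`, and identical seeds reproduce
identical validation curves.

## The synthetic generator, and what it does not show

`generate_synthetic()` emulates the regime the method targets: a large
canvas (default 256×256) with several (3–8) small bright objects of varied
scale (radii 5–20 px, i.e. diameters 10–40 px) on a dark background with
mild Gaussian noise (sd 0.05). Objects are ellipses whose radius is
modulated by low-frequency radial noise (three cosine harmonics, shrink-only
so each object stays inside its bounding circle), giving irregular,
cell-like boundaries. Placement respects a minimum separation (default 2 px;
0 permits overlap), ground truth is the exact rasterized union, and the
whole dataset is a pure function of the seed.

Two deterministic oracle segmenters make every pipeline stage testable
without training: a threshold oracle (foreground where intensity exceeds a
cut — exact on noise-free images) and a ground-truth reader (returns its
input as scores; fed the ground truth as image, it turns the pipeline into
pure geometry). `synth_exact_fit()` additionally builds images whose
padded, squared crop boxes are *exactly* S×S on a downscale-aligned grid,
so with oracle segmenters the full pipeline must reproduce the ground truth
bit-for-bit — a strong wiring test.

What passing these tests does *not* show: the synthetic images are
intensity-separable, single-channel, and noise-stationary; real microscopy,
endoscopy and CT data have texture, illumination gradients, ambiguous
boundaries and annotation noise. Results on the generator demonstrate that
the *pipeline machinery* is correct and that crop-based training recovers
resolution lost to downscaling — not that any particular clinical
performance level will be reached.

## The scaled-down comparison

The package's headline check (also what `scripts/acceptance.R` recomputes)
contrasts the two approaches under identical conditions: 200 cells-like
256×256 images at S = 64 (a 4× downscaling factor), split 140/20/40 into
train/validation/held-out test. The baseline U-Net trains on downscaled
pairs and is reused as the rough stage; the fine network trains on
jittered ground-truth crops resampled every epoch. Both are evaluated at
the original 256×256 resolution (the baseline's prediction upscaled
nearest-neighbour first). The expectation is directional: the two-stage
pipeline exceeds the baseline on mean DSC and, especially, mean recall —
small objects that all but vanish at 64×64 survive in crops, which are
near-native resolution for this object-size regime.

Problem sizes here (depth 2, base 8 channels, 20 epochs, 200 images) are
the package's desk-scale choice: large enough that the comparison is
stable across seeds, small enough to run on a single CPU in minutes.

## Known limitations

* 2D only; CT volumes are handled slice-wise. Nothing in the design is
  2D-specific — a 3D extension needs 3D boxes and backbones.
* Fusion is hard OR over binarized crops; soft-score fusion or overlap
  averaging is out of scope.
* One crop per object and one pass; no iterative re-segmentation.
* Objects larger than the effective crop capacity (larger than about
  $S - 2k$ at native resolution) are downscaled within their crop, so the
  method's advantage shrinks as object size approaches image size.
* Inference cost grows with the number of detected objects, since each
  crop is segmented separately.
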