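# Training-sample preparation for the fine network: ground-truth crop
# regions, random component choice, bounding-box jitter, whole-image
# fallback, geometric augmentation, CT intensity windowing.

#' Bounding-box jitter configuration
#'
#' Training-time perturbation of crop boxes: an integer offset drawn
#' uniformly from `[-max_jitter, +max_jitter]` is added independently to
#' each of the box's left, top, width and height. This makes the fine
#' network robust to the imperfect boxes produced by the rough network at
#' inference time.
#'
#' @param max_jitter Maximum absolute offset in pixels (default 16).
#' @param rng_seed Optional integer; when given, sampling helpers seed R's
#'   RNG with it once before drawing. `NULL` (default) uses the current RNG
#'   stream.
#' @return An object of class `"jitter_config"`.
#' @export
jitter_config <- function(max_jitter = 16L, rng_seed = NULL) {
  max_jitter <- as.integer(max_jitter)
  stopifnot(max_jitter >= 0)
  if (!is.null(rng_seed)) stopifnot(length(rng_seed) == 1)
  structure(list(max_jitter = max_jitter, rng_seed = rng_seed),
            class = "jitter_config")
}

#' Geometric augmentation configuration
#'
#' Train-time augmentation preset: with probability `affine_prob` an affine
#' transform (uniform translation of +/- `translate_frac` of the image size,
#' scaling of +/- `scale_frac`, rotation of +/- `rotate_deg` degrees about
#' the image centre), plus an independent horizontal flip with probability
#' `hflip_prob`. Defaults follow the CT training recipe: 50% affine with
#' +/-6.25% translation, +/-10% scale, +/-14 degrees, and 30% flip.
#'
#' @param affine_prob,hflip_prob Probabilities in `[0, 1]`.
#' @param translate_frac,scale_frac Fractional ranges.
#' @param rotate_deg Rotation range in degrees.
#' @return An object of class `"augment_config"`.
#' @export
augment_config <- function(affine_prob = 0.5, translate_frac = 0.0625,
                           scale_frac = 0.10, rotate_deg = 14,
                           hflip_prob = 0.3) {
  stopifnot(affine_prob >= 0, affine_prob <= 1,
            hflip_prob >= 0, hflip_prob <= 1,
            translate_frac >= 0, scale_frac >= 0, rotate_deg >= 0)
  structure(list(affine_prob = affine_prob, translate_frac = translate_frac,
                 scale_frac = scale_frac, rotate_deg = rotate_deg,
                 hflip_prob = hflip_prob),
            class = "augment_config")
}

#' Crop regions from a ground-truth mask
#'
#' The same box pipeline as [extract_rois()] (tight component box -> noise
#' filter -> square -> pad -> shift) but with components taken directly from
#' the full-resolution ground truth instead of a rough network output. Used
#' to build training crops for the fine network.
#'
#' @param gt_mask Binary matrix at full resolution.
#' @param size An [image_size()] matching `gt_mask`.
#' @param cfg An [roi_config()].
#' @return Possibly empty list of [bbox()].
#' @export
gt_crop_regions <- function(gt_mask, size, cfg) {
  gt_mask <- as_binary_mask(gt_mask)
  stopifnot(inherits(size, "image_size"),
            nrow(gt_mask) == size$height, ncol(gt_mask) == size$width)
  extract_rois(gt_mask, size, cfg)
}

#' Jitter a bounding box
#'
#' Adds four independent integer offsets, each uniform on
#' `[-max_jitter, +max_jitter]`, to the box's left, top, width and height.
#' Dimensions that become non-positive are clamped to 1 pixel; the caller
#' shifts the result into image bounds.
#'
#' @param box A [bbox()].
#' @param cfg A [jitter_config()].
#' @return The perturbed [bbox()] (unchanged when `max_jitter` is 0).
#' @export
jitter_box <- function(box, cfg) {
  stopifnot(inherits(box, "bbox"), inherits(cfg, "jitter_config"))
  m <- cfg$max_jitter
  if (m == 0L) return(box)
  d <- sample.int(2L * m + 1L, 4L, replace = TRUE) - m - 1L
  bbox(box$left + d[1], box$top + d[2],
       max(1L, box$width + d[3]), max(1L, box$height + d[4]))
}

#' Sample one fine-network training pair
#'
#' Picks one ground-truth crop region uniformly at random, jitters it,
#' shifts it into bounds, crops the image and the mask with the same box,
#' and resizes both to `S x S` (nearest-neighbour for the mask). When the
#' ground truth has no usable crop region, the whole image and mask are
#' downscaled to `S x S` instead, so empty images still contribute
#' negative training signal.
#'
#' @param image Full-resolution matrix or H x W x C array.
#' @param gt_mask Binary matrix of the same H x W.
#' @param cfg An [roi_config()].
#' @param jit A [jitter_config()].
#' @param image_mode Resize mode for the image (`"nearest"` default, the
#'   mode used for all resizing; masks always use nearest).
#' @return `list(image = <S x S[, C] array>, mask = <S x S binary matrix>,
#'   box = <bbox or NULL>)`.
#' @export
sample_training_crop <- function(image, gt_mask, cfg, jit = jitter_config(),
                                 image_mode = "nearest") {
  gt_mask <- as_binary_mask(gt_mask)
  d <- dim(image)
  if (d[1] != nrow(gt_mask) || d[2] != ncol(gt_mask))
    stop("image and ground-truth mask shapes differ")
  size <- size_of(image)
  s_sz <- image_size(cfg$input_size, cfg$input_size)
  if (!is.null(jit$rng_seed)) set.seed(jit$rng_seed)
  regions <- gt_crop_regions(gt_mask, size, cfg)
  if (length(regions) == 0) {
    return(list(image = resize_image(image, s_sz, mode = image_mode),
                mask = resize_image(gt_mask, s_sz, mode = "nearest"),
                box = NULL))
  }
  pick <- regions[[sample.int(length(regions), 1L)]]
  b <- shift_to_image_region(jitter_box(pick, jit), size)
  list(image = resize_image(crop(image, b), s_sz, mode = image_mode),
       mask = resize_image(crop(gt_mask, b), s_sz, mode = "nearest"),
       box = b)
}

# inverse-map affine resampling about the image centre.
# theta in radians; scale > 0; (ty, tx) translation in pixels.
# mode "bilinear" for images, "nearest" for masks.
affine_resample <- function(plane, theta, scale, ty, tx, mode) {
  h <- nrow(plane); w <- ncol(plane)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # output pixel centres
  yy <- matrix(seq_len(h), h, w) - cy - ty
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx - tx
  # inverse rotation+scale
  ct <- cos(theta) / scale; st <- sin(theta) / scale
  sy <- ct * yy - st * xx + cy
  sx <- st * yy + ct * xx + cx
  if (mode == "nearest") {
    ry <- pmin(pmax(round(sy), 1), h)
    rx <- pmin(pmax(round(sx), 1), w)
    out <- plane[cbind(as.vector(ry), as.vector(rx))]
  } else {
    sy <- pmin(pmax(sy, 1), h); sx <- pmin(pmax(sx, 1), w)
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
    fy <- sy - y0; fx <- sx - x0
    ix <- function(r, c) plane[cbind(as.vector(r), as.vector(c))]
    out <- ix(y0, x0) * (1 - fy) * (1 - fx) + ix(y1, x0) * fy * (1 - fx) +
      ix(y0, x1) * (1 - fy) * fx + ix(y1, x1) * fy * fx
  }
  matrix(out, h, w)
}

#' Geometric augmentation of an image/mask pair
#'
#' Applies the same randomly drawn transform to image (bilinear) and mask
#' (nearest), so the pair stays aligned. See [augment_config()] for the
#' transform family and defaults.
#'
#' @param image Matrix or H x W x C array.
#' @param mask Binary matrix of the same H x W.
#' @param cfg An [augment_config()].
#' @return `list(image = ..., mask = ...)` with unchanged shapes.
#' @export
augment <- function(image, mask, cfg = augment_config()) {
  mask <- as_binary_mask(mask)
  stopifnot(inherits(cfg, "augment_config"))
  d <- dim(image)
  stopifnot(d[1] == nrow(mask), d[2] == ncol(mask))
  do_affine <- stats::runif(1) < cfg$affine_prob
  do_flip <- stats::runif(1) < cfg$hflip_prob
  if (do_affine) {
    theta <- stats::runif(1, -cfg$rotate_deg, cfg$rotate_deg) * pi / 180
    scale <- 1 + stats::runif(1, -cfg$scale_frac, cfg$scale_frac)
    ty <- stats::runif(1, -cfg$translate_frac, cfg$translate_frac) * d[1]
    tx <- stats::runif(1, -cfg$translate_frac, cfg$translate_frac) * d[2]
    per_plane <- function(p, mode) affine_resample(p, theta, scale, ty, tx, mode)
    if (length(d) == 2) {
      image <- per_plane(image, "bilinear")
    } else {
      for (k in seq_len(d[3])) image[, , k] <- per_plane(image[, , k], "bilinear")
    }
    mask <- as_binary_mask(per_plane(mask, "nearest"))
  }
  if (do_flip) {
    flip <- function(p) p[, rev(seq_len(ncol(p))), drop = FALSE]
    if (length(d) == 2) image <- flip(image)
    else for (k in seq_len(d[3])) image[, , k] <- flip(image[, , k])
    mask <- flip(mask)
  }
  list(image = image, mask = mask)
}

#' CT intensity windowing
#'
#' Clips a CT slice to a Hounsfield-unit window, maps the window linearly
#' onto `[-0.5, 0.5]`, and zero-centres by subtracting 0.1, so the output
#' range is `[-0.6, 0.4]`. The default window 200-500 HU isolates
#' contrast-enhanced vascular structures.
#'
#' @param slice Numeric matrix (or array) of HU values.
#' @param lo,hi Window bounds in HU, `hi > lo`.
#' @return Windowed, normalized array of the same shape.
#' @examples
#' ct_window(matrix(c(100, 350, 600), 1, 3))  # -0.6, -0.1, 0.4
#' @export
ct_window <- function(slice, lo = 200, hi = 500) {
  stopifnot(is.numeric(slice), length(lo) == 1, length(hi) == 1)
  if (!(hi > lo)) stop("window requires hi > lo")
  (pmin(pmax(slice, lo), hi) - lo) / (hi - lo) - 0.5 - 0.1
}
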