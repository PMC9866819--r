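Package: seg2seg
Title: Segment-then-Segment: Crop-Based Coarse-to-Fine Segmentation for Large Biomedical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage crop-based segmentation for large biomedical images
    (microscopy, endoscopy, CT slices). A rough network segments a heavily
    downscaled image to locate objects; each object's padded, squared bounding
    box is cropped from the full-resolution image and segmented by a second,
    specially trained network; per-crop masks are fused by pixel-wise OR into a
    full-resolution output. Includes bounding-box geometry, connected-component
    ROI extraction, crop/resize/fuse operations, training-sample preparation
    with bounding-box jitter augmentation, a compact trainable U-Net backend,
    Dice/IoU/precision/recall scoring with upscaled evaluation, and a synthetic
    multi-object image generator with oracle segmenters for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    png,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
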