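# Cropping, resizing, binarization, fusion and the full two-stage
# inference procedure.

#' Crop an image by a bounding box
#'
#' @param image Matrix (H x W) or array (H x W x C).
#' @param box A [bbox()] fully inside the image (shift it first if needed).
#' @return Array of shape `(box$height, box$width[, C])`; pixel `(r, c)` of
#'   the crop equals image pixel `(box$top + r, box$left + c)` (0-based).
#' @examples
#' img <- matrix(1:16, 4, 4)
#' crop(img, bbox(1, 1, 2, 2))
#' @export
crop <- function(image, box) {
  stopifnot(inherits(box, "bbox"))
  d <- dim(image)
  if (box$left < 0 || box$top < 0 ||
      box$left + box$width > d[2] || box$top + box$height > d[1])
    stop("box extends outside the image; shift_to_image_region first")
  rows <- (box$top + 1L):(box$top + box$height)
  cols <- (box$left + 1L):(box$left + box$width)
  if (length(d) == 2) image[rows, cols, drop = FALSE]
  else image[rows, cols, , drop = FALSE]
}

# nearest-neighbour source indices for one axis (1-based):
# src = floor(dst * n_src / n_dst)
nn_index <- function(n_dst, n_src) {
  floor((seq_len(n_dst) - 1) * n_src / n_dst) + 1L
}

# bilinear sample of a single-channel matrix at fractional (half-pixel
# centred) coordinates
bilinear_axis <- function(n_dst, n_src) {
  s <- (seq_len(n_dst) - 0.5) * n_src / n_dst - 0.5
  s <- pmin(pmax(s, 0), n_src - 1)
  i0 <- floor(s)
  list(lo = as.integer(i0) + 1L,
       hi = as.integer(pmin(i0 + 1, n_src - 1)) + 1L,
       w = s - i0)
}

resize_plane <- function(plane, to, mode) {
  h0 <- nrow(plane); w0 <- ncol(plane)
  if (h0 == to$height && w0 == to$width) return(plane)
  if (mode == "nearest") {
    plane[nn_index(to$height, h0), nn_index(to$width, w0), drop = FALSE]
  } else {
    ry <- bilinear_axis(to$height, h0)
    rx <- bilinear_axis(to$width, w0)
    tl <- plane[ry$lo, rx$lo, drop = FALSE]
    bl <- plane[ry$hi, rx$lo, drop = FALSE]
    tr <- plane[ry$lo, rx$hi, drop = FALSE]
    br <- plane[ry$hi, rx$hi, drop = FALSE]
    wy <- matrix(ry$w, to$height, to$width)
    wx <- matrix(rx$w, to$height, to$width, byrow = TRUE)
    (tl * (1 - wy) + bl * wy) * (1 - wx) + (tr * (1 - wy) + br * wy) * wx
  }
}

#' Resize an image or mask
#'
#' Nearest-neighbour (default, used for all mask resizing so binary masks
#' stay binary) or bilinear resampling. The nearest index map is
#' `src = floor(dst * n_src / n_dst)`; resizing to the same size is the
#' identity.
#'
#' @param image Matrix (H x W) or array (H x W x C).
#' @param to An [image_size()].
#' @param mode `"nearest"` or `"bilinear"`.
#' @return Resized array with the same channel count.
#' @examples
#' m <- matrix(c(1, 0, 0, 0), 2, 2)
#' resize_image(m, image_size(4, 4))
#' @export
resize_image <- function(image, to, mode = c("nearest", "bilinear")) {
  mode <- match.arg(mode)
  stopifnot(inherits(to, "image_size"))
  d <- dim(image)
  int_in <- is.integer(image)
  out <- if (length(d) == 2) {
    resize_plane(image, to, mode)
  } else {
    res <- array(0, dim = c(to$height, to$width, d[3]))
    for (k in seq_len(d[3])) res[, , k] <- resize_plane(image[, , k], to, mode)
    res
  }
  if (int_in && mode == "nearest") storage.mode(out) <- "integer"
  out
}

#' Threshold a score mask into a binary mask
#'
#' @param scores Numeric matrix of per-pixel scores in `[0, 1]`.
#' @param threshold Scores `>= threshold` become foreground (default 0.5).
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize <- function(scores, threshold = 0.5) {
  stopifnot(is.matrix(scores), length(threshold) == 1)
  out <- (scores >= threshold) * 1L
  dim(out) <- dim(scores)
  out
}

#' Fuse per-crop masks into a full-resolution mask
#'
#' Places each crop mask at its box position and combines overlaps with a
#' pixel-wise logical OR (equivalently, a per-pixel maximum over binary
#' masks). Fusion is therefore commutative and idempotent: crop order and
#' duplicated crops never change the result. An empty list yields an
#' all-background mask.
#'
#' @param crop_masks List of `list(mask = <binary matrix>, box = <bbox>)`
#'   pairs; each mask's shape must equal its box's `(height, width)`.
#' @param size Output [image_size()].
#' @return Binary integer matrix of shape `(size$height, size$width)`.
#' @examples
#' a <- list(mask = matrix(1L, 2, 2), box = bbox(0, 0, 2, 2))
#' b <- list(mask = matrix(1L, 2, 2), box = bbox(1, 1, 2, 2))
#' sum(fuse(list(a, b), image_size(4, 4)))  # union of 7 pixels
#' @export
fuse <- function(crop_masks, size) {
  stopifnot(inherits(size, "image_size"), is.list(crop_masks))
  out <- matrix(0L, size$height, size$width)
  for (cm in crop_masks) {
    m <- as_binary_mask(cm$mask); b <- cm$box
    stopifnot(inherits(b, "bbox"))
    if (nrow(m) != b$height || ncol(m) != b$width)
      stop("crop mask shape does not match its box")
    if (b$left < 0 || b$top < 0 ||
        b$left + b$width > size$width || b$top + b$height > size$height)
      stop("box extends outside the output image")
    rows <- (b$top + 1L):(b$top + b$height)
    cols <- (b$left + 1L):(b$left + b$width)
    out[rows, cols] <- pmax(out[rows, cols], m)
  }
  out
}

#' Segmenter contract
#'
#' A segmenter is any model that maps an `S x S` image (matrix or
#' `S x S x C` array) to an `S x S` matrix of scores in `[0, 1]`. Both
#' pipeline stages — the rough network on the downscaled image and the fine
#' network on full-resolution crops — satisfy this contract, as do the
#' oracle segmenters used in tests.
#'
#' @param predict_fn Function `(image) -> score matrix`.
#' @param input_size Expected input size `S`.
#' @param channels Expected channel count (default 1).
#' @param name Optional label for printing.
#' @return An object of class `"segmenter"`.
#' @seealso [segmenter_predict()], [unet_segmenter()], [oracle_segmenter()]
#' @export
segmenter <- function(predict_fn, input_size, channels = 1L, name = "segmenter") {
  stopifnot(is.function(predict_fn), input_size >= 1)
  structure(list(predict = predict_fn,
                 input_size = as.integer(input_size),
                 channels = as.integer(channels), name = name),
            class = "segmenter")
}

#' @export
print.segmenter <- function(x, ...) {
  cat(sprintf("<segmenter '%s' S=%d C=%d>\n", x$name, x$input_size, x$channels))
  invisible(x)
}

#' Run a segmenter on one input image
#'
#' Validates the contract: the input must be `S x S`, and the returned
#' scores must be an `S x S` matrix in `[0, 1]`.
#'
#' @param seg A [segmenter()].
#' @param image `S x S` matrix or `S x S x C` array.
#' @return `S x S` numeric score matrix.
#' @export
segmenter_predict <- function(seg, image) {
  stopifnot(inherits(seg, "segmenter"))
  d <- dim(image)
  if (d[1] != seg$input_size || d[2] != seg$input_size)
    stop(sprintf("segmenter '%s' expects %dx%d input, got %dx%d",
                 seg$name, seg$input_size, seg$input_size, d[1], d[2]))
  scores <- seg$predict(image)
  stopifnot(is.matrix(scores),
            nrow(scores) == seg$input_size, ncol(scores) == seg$input_size)
  if (any(scores < -1e-9) || any(scores > 1 + 1e-9))
    stop("segmenter scores must lie in [0, 1]")
  pmin(pmax(scores, 0), 1)
}

# match an image's channel count to what a segmenter expects
match_channels <- function(image, seg) {
  d <- dim(image)
  c_in <- if (length(d) == 2) 1L else d[3]
  if (c_in == seg$channels) return(image)
  if (seg$channels == 1L && c_in > 1L) {
    # average channels down to grayscale
    return(apply(image, c(1, 2), mean))
  }
  stop(sprintf("segmenter '%s' expects %d channel(s), image has %d",
               seg$name, seg$channels, c_in))
}

#' Two-stage crop-based segmentation of one image
#'
#' The full inference procedure. The image is downscaled to `S x S` and
#' segmented by the rough network; each connected component of the rough
#' mask (resized back to full resolution) yields a squared, context-padded
#' crop box; each crop is taken from the image at original resolution,
#' resized to `S x S`, segmented by the fine network, binarized, resized
#' back to the box size, and all crop masks are fused by pixel-wise OR. If
#' no salient region survives (blank rough mask, or all components below
#' the noise threshold), the output is all background.
#'
#' @param image Full-resolution matrix (H x W) or array (H x W x C).
#' @param rough,fine [segmenter()] objects sharing `cfg$input_size`.
#' @param cfg An [roi_config()].
#' @param threshold Score binarization threshold (default 0.5), applied to
#'   both stages.
#' @return Binary integer matrix of shape H x W.
#' @examples
#' # a threshold "network" suffices on intensity-separable images
#' s <- oracle_segmenter("threshold", input_size = 64, cut = 0.5)
#' img <- matrix(0, 256, 256); img[100:140, 60:120] <- 1
#' y <- segment_then_segment(img, s, s, roi_config(64))
#' sum(y)
#' @export
segment_then_segment <- function(image, rough, fine, cfg, threshold = 0.5) {
  stopifnot(inherits(rough, "segmenter"), inherits(fine, "segmenter"),
            inherits(cfg, "roi_config"))
  if (rough$input_size != cfg$input_size || fine$input_size != cfg$input_size)
    stop("rough and fine segmenters must share cfg$input_size")
  full <- size_of(image)
  s_sz <- image_size(cfg$input_size, cfg$input_size)

  small <- resize_image(match_channels(image, rough), s_sz, mode = "nearest")
  rough_mask <- binarize(segmenter_predict(rough, small), threshold)
  boxes <- extract_rois(rough_mask, full, cfg)
  if (length(boxes) == 0) return(matrix(0L, full$height, full$width))

  placed <- lapply(boxes, function(b) {
    piece <- resize_image(match_channels(crop(image, b), fine), s_sz,
                          mode = "nearest")
    m <- binarize(segmenter_predict(fine, piece), threshold)
    m <- resize_image(m, image_size(b$height, b$width), mode = "nearest")
    list(mask = m, box = b)
  })
  fuse(placed, full)
}
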