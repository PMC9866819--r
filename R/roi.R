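# ROI extraction: rough binary mask -> list of salient crop boxes.

as_binary_mask <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1L
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "integer"
  if (any(is.na(mask)) || any(mask != 0L & mask != 1L))
    stop("mask must be binary (0/1)")
  mask
}

#' Crop-extraction configuration
#'
#' Holds the shared network input size `S`, the context padding `k`
#' (default `floor(S/8)`), the minimum crop size below which rough-mask
#' components are treated as noise, and the component connectivity.
#'
#' @param input_size Network input size `S` (images and crops are resized to
#'   `S x S`); must be >= 8.
#' @param padding Context padding added on each of the four sides of a crop
#'   box, in full-resolution pixels. Default `floor(input_size / 8)`.
#' @param min_crop_px Components whose tight bounding box is narrower or
#'   shorter than this many pixels are discarded as noise (default 5).
#' @param connectivity Pixel connectivity for components, 8 (default) or 4.
#' @return An object of class `"roi_config"`.
#' @examples
#' roi_config(256)   # S = 256, k = 32
#' @export
roi_config <- function(input_size, padding = NULL, min_crop_px = 5L,
                       connectivity = 8L) {
  input_size <- as.integer(input_size)
  stopifnot(length(input_size) == 1, input_size >= 8)
  if (is.null(padding)) padding <- input_size %/% 8L
  padding <- as.integer(padding)
  min_crop_px <- as.integer(min_crop_px)
  stopifnot(padding >= 0, min_crop_px >= 1, connectivity %in% c(4L, 8L))
  structure(list(input_size = input_size, padding = padding,
                 min_crop_px = min_crop_px,
                 connectivity = as.integer(connectivity)),
            class = "roi_config")
}

#' @export
print.roi_config <- function(x, ...) {
  cat(sprintf("<roi_config S=%d k=%d min_crop=%dpx conn=%d>\n",
              x$input_size, x$padding, x$min_crop_px, x$connectivity))
  invisible(x)
}

#' Label connected components of a binary mask
#'
#' Partitions foreground pixels into maximal connected components
#' (8-connectivity by default, so diagonal touches merge). Components are
#' numbered deterministically: ordered by the minimum row, then minimum
#' column, over each component's pixels.
#'
#' @param mask Binary matrix (0/1 or logical).
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape; 0 is background, components are
#'   numbered 1..N.
#' @examples
#' m <- matrix(0L, 8, 8); m[2:3, 2:3] <- 1L; m[6:7, 5:6] <- 1L
#' max(label_components(m))  # 2
#' @export
label_components <- function(mask, connectivity = 8L) {
  mask <- as_binary_mask(mask)
  stopifnot(connectivity %in% c(4L, 8L))
  cpp_label_components(mask, as.integer(connectivity))
}

#' Tight bounding box of a labeled component
#'
#' @param labels Integer label matrix from [label_components()].
#' @param id Component number (>= 1).
#' @return The tightest [bbox()] containing every pixel of the component.
#' @export
component_bbox <- function(labels, id) {
  stopifnot(is.matrix(labels), length(id) == 1, id >= 1)
  w <- which(labels == id, arr.ind = TRUE)
  if (nrow(w) == 0) stop("component ", id, " is empty")
  r0 <- min(w[, 1]) - 1L; r1 <- max(w[, 1]) - 1L
  c0 <- min(w[, 2]) - 1L; c1 <- max(w[, 2]) - 1L
  bbox(c0, r0, c1 - c0 + 1L, r1 - r0 + 1L)
}

# square -> pad -> shift, the per-component box pipeline
prepare_box <- function(box, size, cfg) {
  shift_to_image_region(pad_box(square_box(box), cfg$padding), size)
}

#' Extract salient crop regions from a rough segmentation
#'
#' Turns a rough binary mask into the list of full-resolution crop boxes:
#' the mask is resized (nearest-neighbour) to the target resolution, each
#' connected component yields its tight bounding box, components whose tight
#' box is narrower or shorter than `cfg$min_crop_px` are discarded as noise,
#' and each surviving box is squared, padded by `cfg$padding` on every side,
#' and shifted to lie fully inside the image.
#'
#' @param rough_mask Binary matrix, either at the network resolution
#'   (`S x S`) or already at the target resolution.
#' @param target An [image_size()]: the full image resolution.
#' @param cfg An [roi_config()].
#' @return Possibly empty list of [bbox()] in deterministic (top-left-most
#'   first) order.
#' @examples
#' m <- matrix(0L, 64, 64); m[10:19, 12:21] <- 1L
#' extract_rois(m, image_size(256, 256), roi_config(64))
#' @export
extract_rois <- function(rough_mask, target, cfg) {
  rough_mask <- as_binary_mask(rough_mask)
  stopifnot(inherits(target, "image_size"), inherits(cfg, "roi_config"))
  if (nrow(rough_mask) != target$height || ncol(rough_mask) != target$width)
    rough_mask <- resize_image(rough_mask, target, mode = "nearest")
  labels <- label_components(rough_mask, cfg$connectivity)
  n <- max(labels)
  if (n == 0) return(list())
  out <- list()
  for (i in seq_len(n)) {
    tight <- component_bbox(labels, i)
    if (tight$width < cfg$min_crop_px || tight$height < cfg$min_crop_px)
      next
    out[[length(out) + 1L]] <- prepare_box(tight, target, cfg)
  }
  out
}
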