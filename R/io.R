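# PNG image/mask I/O for the command-line front-end. Grayscale images load
# as H x W matrices in [0, 1]; RGB(A) images as H x W x C arrays. Masks are
# written as 8-bit PNGs with foreground 255.

#' Read an image or binary mask from PNG
#'
#' @param path PNG file path.
#' @return `read_image_png`: numeric matrix (grayscale) or H x W x C array,
#'   values in `[0, 1]`. `read_mask_png`: binary integer matrix (pixels
#'   >= 0.5 are foreground; multi-channel files use the first channel).
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 1) dim(img) <- dim(img)[1:2]
  img
}

#' @rdname read_image_png
#' @export
read_mask_png <- function(path) {
  img <- read_image_png(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  binarize(img, 0.5)
}

#' Write an image or binary mask to PNG
#'
#' @param image Numeric matrix/array with values in `[0, 1]`.
#' @param mask Binary matrix; written with foreground as 255.
#' @param path Output PNG file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_binary_mask(mask) + 0, path)
  invisible(path)
}
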