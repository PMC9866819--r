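#' Axis-aligned bounding box
#'
#' Boxes use 0-based pixel coordinates with half-open extent: the covered
#' pixel set is rows `[top, top + height)` by columns `[left, left + width)`.
#' This makes crop slicing and size arithmetic unambiguous: `width` and
#' `height` are exact pixel counts.
#'
#' @param left Column of the first included pixel (0-based integer).
#' @param top Row of the first included pixel (0-based integer).
#' @param width,height Box extent in pixels; both must be >= 1.
#' @return An object of class `"bbox"`.
#' @examples
#' bbox(10, 20, 4, 8)
#' @export
bbox <- function(left, top, width, height) {
  stopifnot(length(left) == 1, length(top) == 1,
            length(width) == 1, length(height) == 1)
  left <- as.integer(round(left)); top <- as.integer(round(top))
  width <- as.integer(round(width)); height <- as.integer(round(height))
  if (width < 1L || height < 1L)
    stop("bbox width and height must be >= 1")
  structure(list(left = left, top = top, width = width, height = height),
            class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox left=%d top=%d width=%d height=%d>\n",
              x$left, x$top, x$width, x$height))
  invisible(x)
}

#' @export
format.bbox <- function(x, ...) {
  sprintf("(%d, %d, %dx%d)", x$left, x$top, x$width, x$height)
}

#' Image size
#'
#' @param height,width Image extent in pixels, both >= 1.
#' @return An object of class `"image_size"` with fields `height`, `width`.
#' @examples
#' image_size(512, 666)
#' @export
image_size <- function(height, width) {
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(length(height) == 1, length(width) == 1, height >= 1, width >= 1)
  structure(list(height = height, width = width), class = "image_size")
}

#' @export
print.image_size <- function(x, ...) {
  cat(sprintf("<image_size %dx%d (HxW)>\n", x$height, x$width))
  invisible(x)
}

size_of <- function(img) {
  d <- dim(img)
  image_size(d[1], d[2])
}

#' Square a bounding box
#'
#' Sets both dimensions to `max(width, height)`, keeping the top-left corner
#' anchored. Idempotent. The grown box may extend beyond the image; callers
#' follow with [shift_to_image_region()].
#'
#' @param box A [bbox()].
#' @return A square [bbox()].
#' @examples
#' square_box(bbox(10, 20, 4, 8))  # -> 8x8 at (10, 20)
#' @export
square_box <- function(box) {
  stopifnot(inherits(box, "bbox"))
  side <- max(box$width, box$height)
  bbox(box$left, box$top, side, side)
}

#' Pad a bounding box symmetrically
#'
#' Adds `k` pixels of context on each of the four sides, so each dimension
#' grows by `2k`. In the crop pipeline `k = floor(S/8)` for an SxS network
#' input, which keeps surroundings of the object inside the crop and reduces
#' false negatives near the object boundary. The result may extend outside
#' the image; callers follow with [shift_to_image_region()].
#'
#' @param box A [bbox()].
#' @param k Non-negative integer padding per side.
#' @return The padded [bbox()].
#' @examples
#' pad_box(bbox(100, 100, 64, 64), 32)  # -> 128x128 at (68, 68)
#' @export
pad_box <- function(box, k) {
  stopifnot(inherits(box, "bbox"), length(k) == 1)
  k <- as.integer(k)
  if (is.na(k) || k < 0L) stop("padding k must be >= 0")
  bbox(box$left - k, box$top - k, box$width + 2L * k, box$height + 2L * k)
}

#' Shift a box to lie fully inside an image
#'
#' Translates the box (keeping width and height) so it fits in
#' `[0, W) x [0, H)`. A box larger than the image in either dimension is
#' clamped to the full image extent in that dimension with origin 0.
#'
#' @param box A [bbox()].
#' @param size An [image_size()].
#' @return A [bbox()] fully inside the image.
#' @examples
#' shift_to_image_region(bbox(-5, 10, 20, 20), image_size(100, 100))
#' @export
shift_to_image_region <- function(box, size) {
  stopifnot(inherits(box, "bbox"), inherits(size, "image_size"))
  w <- min(box$width, size$width)
  h <- min(box$height, size$height)
  left <- min(max(box$left, 0L), size$width - w)
  top <- min(max(box$top, 0L), size$height - h)
  bbox(left, top, w, h)
}

#' Scale a box between image resolutions
#'
#' Maps a box from one image-coordinate space to another (e.g. from the SxS
#' rough-mask space to the full WxH image space). Each coordinate and
#' dimension is multiplied by the per-axis ratio and rounded half-to-even;
#' dimensions are floored at 1 pixel.
#'
#' @param box A [bbox()].
#' @param from,to [image_size()] of the source and destination spaces.
#' @return The rescaled [bbox()].
#' @examples
#' scale_box(bbox(8, 8, 16, 16), image_size(64, 64), image_size(256, 256))
#' @export
scale_box <- function(box, from, to) {
  stopifnot(inherits(box, "bbox"),
            inherits(from, "image_size"), inherits(to, "image_size"))
  sy <- to$height / from$height
  sx <- to$width / from$width
  bbox(round(box$left * sx), round(box$top * sy),
       max(1, round(box$width * sx)), max(1, round(box$height * sy)))
}

#' Convert a list of boxes to a data frame
#'
#' @param boxes A list of [bbox()] objects.
#' @return A data frame with columns `left`, `top`, `width`, `height`
#'   (0-based coordinates).
#' @export
boxes_to_df <- function(boxes) {
  stopifnot(is.list(boxes))
  if (length(boxes) == 0)
    return(data.frame(left = integer(), top = integer(),
                      width = integer(), height = integer()))
  data.frame(left = vapply(boxes, `[[`, integer(1), "left"),
             top = vapply(boxes, `[[`, integer(1), "top"),
             width = vapply(boxes, `[[`, integer(1), "width"),
             height = vapply(boxes, `[[`, integer(1), "height"))
}

#' Convert a data frame of box records to a list of boxes
#'
#' @param df Data frame with columns `left`, `top`, `width`, `height`.
#' @return List of [bbox()] objects.
#' @export
df_to_boxes <- function(df) {
  stopifnot(all(c("left", "top", "width", "height") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i)
    bbox(df$left[i], df$top[i], df$width[i], df$height[i]))
}

#' Read / write boxes as CSV
#'
#' Plain 4-column CSV interchange (`left,top,width,height`, 0-based), used by
#' the command-line front-end.
#'
#' @param boxes List of [bbox()] objects.
#' @param path File path.
#' @return `write_boxes` returns `path` invisibly; `read_boxes` a list of boxes.
#' @export
write_boxes <- function(boxes, path) {
  utils::write.csv(boxes_to_df(boxes), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boxes
#' @export
read_boxes <- function(path) {
  df_to_boxes(utils::read.csv(path))
}
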