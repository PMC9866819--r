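# Synthetic multi-object images with exact ground truth, plus deterministic
# oracle segmenters. Emulates the regime the crop-based pipeline targets:
# large canvases carrying several small objects of varied scale.

#' Synthetic dataset configuration
#'
#' Defaults describe a "cells-like" regime: a 256x256 canvas with 3-8
#' bright, irregular blobs of radius 5-20 px (object diameters 10-40 px) on
#' a dark background with mild Gaussian noise.
#'
#' @param canvas An [image_size()] (default 256x256).
#' @param n_objects Integer range `c(min, max)` of objects per image.
#' @param radius_px Range `c(min, max)` of object base radii in pixels
#'   (min >= 2).
#' @param shape `"blob"` (ellipse with low-frequency radial perturbation,
#'   irregular boundaries like cells or polyps) or `"ellipse"` (smooth).
#' @param intensity_fg,intensity_bg Ranges for per-object foreground and
#'   per-image background intensity.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param min_separation Minimum gap in pixels between object boundaries
#'   (measured via bounding circles); 0 permits overlap.
#' @param seed Integer seed; generation is a pure function of the
#'   configuration and the number of images.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(canvas = image_size(256, 256),
                         n_objects = c(3L, 8L),
                         radius_px = c(5L, 20L),
                         shape = c("blob", "ellipse"),
                         intensity_fg = c(0.7, 0.9),
                         intensity_bg = c(0.1, 0.3),
                         noise_sd = 0.05,
                         min_separation = 2L,
                         seed = 2022L) {
  shape <- match.arg(shape)
  stopifnot(inherits(canvas, "image_size"),
            length(n_objects) == 2, n_objects[1] <= n_objects[2],
            n_objects[1] >= 0,
            length(radius_px) == 2, radius_px[1] >= 2,
            radius_px[1] <= radius_px[2],
            noise_sd >= 0, min_separation >= 0,
            length(intensity_fg) == 2, length(intensity_bg) == 2)
  structure(list(canvas = canvas, n_objects = as.integer(n_objects),
                 radius_px = as.integer(radius_px), shape = shape,
                 intensity_fg = intensity_fg, intensity_bg = intensity_bg,
                 noise_sd = noise_sd,
                 min_separation = as.numeric(min_separation),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config %dx%d n=[%d,%d] r=[%d,%d] %s noise=%.3f seed=%d>\n",
    x$canvas$height, x$canvas$width, x$n_objects[1], x$n_objects[2],
    x$radius_px[1], x$radius_px[2], x$shape, x$noise_sd, x$seed))
  invisible(x)
}

# Rasterize one object into a logical canvas-sized matrix.
# Blob boundary: an ellipse (semi-axes ry, rx, rotated by phi) whose radius
# is modulated by low-frequency radial noise, f(theta) = 1 - amp + sum_k
# a_k cos(k theta + p_k) with k in 2..4 and sum |a_k| <= amp, so the factor
# stays in [1 - 2*amp, 1]: perturbation only shrinks, keeping the object
# inside its bounding circle (bbox <= 2*r + 1 px).
rasterize_object <- function(canvas, cy, cx, ry, rx, phi, shape, amp = 0.15) {
  rmax <- max(ry, rx)
  r0 <- max(1L, floor(cy - rmax)); r1 <- min(canvas$height, ceiling(cy + rmax))
  c0 <- max(1L, floor(cx - rmax)); c1 <- min(canvas$width, ceiling(cx + rmax))
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  u <- cos(phi) * dx + sin(phi) * dy
  v <- -sin(phi) * dx + cos(phi) * dy
  rho <- sqrt((u / rx)^2 + (v / ry)^2)
  if (shape == "blob") {
    a <- stats::runif(3, 0, amp / 3)
    ph <- stats::runif(3, 0, 2 * pi)
    theta <- atan2(v, u)
    f <- 1 - amp +
      a[1] * cos(2 * theta + ph[1]) +
      a[2] * cos(3 * theta + ph[2]) +
      a[3] * cos(4 * theta + ph[3])
  } else {
    f <- 1
  }
  inside <- rho <= f
  out <- matrix(FALSE, canvas$height, canvas$width)
  out[rows, cols] <- inside
  out
}

#' Generate a synthetic segmentation dataset
#'
#' Places `n_objects` non-degenerate shapes per image (placement respects
#' `min_separation`; overlap is permitted at 0); the ground truth is the
#' exact rasterized union of the shapes; additive Gaussian noise is applied
#' to the image only. Fully determined by `cfg$seed`: the same
#' configuration always yields bit-identical datasets.
#'
#' @param cfg A [synth_config()].
#' @param n_images Number of image/mask pairs.
#' @return List of `list(image = <H x W numeric matrix>,
#'   mask = <H x W binary integer matrix>)`.
#' @examples
#' d <- generate_synthetic(synth_config(seed = 1), 2)
#' dim(d[[1]]$image)
#' @export
generate_synthetic <- function(cfg, n_images) {
  stopifnot(inherits(cfg, "synth_config"), n_images >= 1)
  set.seed(cfg$seed)
  H <- cfg$canvas$height; W <- cfg$canvas$width
  lapply(seq_len(n_images), function(i) {
    n <- if (cfg$n_objects[1] == cfg$n_objects[2]) cfg$n_objects[1]
         else sample(cfg$n_objects[1]:cfg$n_objects[2], 1L)
    bg <- stats::runif(1, cfg$intensity_bg[1], cfg$intensity_bg[2])
    img <- matrix(bg, H, W)
    mask <- matrix(FALSE, H, W)
    placed <- matrix(numeric(0), ncol = 3)  # cy, cx, bounding radius
    for (k in seq_len(n)) {
      ok <- FALSE
      for (attempt in seq_len(200L)) {
        ry <- stats::runif(1, cfg$radius_px[1], cfg$radius_px[2])
        rx <- stats::runif(1, cfg$radius_px[1], cfg$radius_px[2])
        rmax <- max(ry, rx)
        if (2 * rmax + 2 > min(H, W)) next
        cy <- stats::runif(1, rmax + 1, H - rmax)
        cx <- stats::runif(1, rmax + 1, W - rmax)
        if (nrow(placed) > 0) {
          dist <- sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2)
          if (any(dist < placed[, 3] + rmax + cfg$min_separation)) next
        }
        phi <- stats::runif(1, 0, pi)
        obj <- rasterize_object(cfg$canvas, cy, cx, ry, rx, phi, cfg$shape)
        fg <- stats::runif(1, cfg$intensity_fg[1], cfg$intensity_fg[2])
        img[obj] <- fg
        mask <- mask | obj
        placed <- rbind(placed, c(cy, cx, rmax))
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not place object ", k, " of ", n,
             " after bounded retries; reduce n_objects/radius or separation")
    }
    if (cfg$noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, sd = cfg$noise_sd), H, W)
    list(image = img, mask = mask * 1L)
  })
}

#' Synthetic images whose crop boxes fit the network input exactly
#'
#' A fixture generator for pipeline-fidelity checks: every object is a disc
#' whose tight bounding box, after squaring and context padding, is exactly
#' `S x S`, and all geometry is aligned to the downscale grid
#' (`canvas / S` must be an integer). With oracle segmenters the two-stage
#' pipeline then involves no lossy rescaling, so its output must reproduce
#' the ground truth bit-exactly. Objects are placed on the low-resolution
#' grid with at least one low-resolution pixel of separation.
#'
#' @param n_images Number of pairs.
#' @param input_size Network input size S.
#' @param padding Context padding k (default `floor(S/8)`).
#' @param canvas Square canvas side in pixels (integer multiple of S).
#' @param n_objects Range `c(min, max)` of objects per image.
#' @param seed RNG seed.
#' @return List of `list(image, mask)` as [generate_synthetic()]; images are
#'   noise-free with foreground 1 and background 0.
#' @export
synth_exact_fit <- function(n_images, input_size = 64L,
                            padding = input_size %/% 8L,
                            canvas = 256L, n_objects = c(1L, 3L),
                            seed = 2022L) {
  input_size <- as.integer(input_size); canvas <- as.integer(canvas)
  padding <- as.integer(padding)
  if (canvas %% input_size != 0)
    stop("canvas must be an integer multiple of input_size")
  f <- canvas %/% input_size
  side_lr <- (input_size - 2L * padding) %/% f   # tight box side, low-res
  if (side_lr * f != input_size - 2L * padding)
    stop("input_size - 2*padding must be divisible by canvas/input_size")
  if (side_lr < 3L) stop("padding leaves no room for objects")
  set.seed(seed)
  s_lr <- canvas %/% f                            # low-res canvas side
  margin <- max(1L, padding %/% f)                # keep padded box inside
  disc <- local({                                 # disc with exact side_lr bbox
    ctr <- (side_lr - 1) / 2
    rr <- matrix(0:(side_lr - 1), side_lr, side_lr)
    cc <- t(rr)
    (rr - ctr)^2 + (cc - ctr)^2 <= (ctr + 0.1)^2
  })
  lapply(seq_len(n_images), function(i) {
    n <- if (n_objects[1] == n_objects[2]) n_objects[1]
         else sample(n_objects[1]:n_objects[2], 1L)
    lr <- matrix(FALSE, s_lr, s_lr)
    anchors <- matrix(numeric(0), ncol = 2)
    for (k in seq_len(n)) {
      for (attempt in seq_len(200L)) {
        r0 <- sample(margin:(s_lr - margin - side_lr), 1L)
        c0 <- sample(margin:(s_lr - margin - side_lr), 1L)
        if (nrow(anchors) > 0 &&
            any(abs(anchors[, 1] - r0) < side_lr + 2 &
                abs(anchors[, 2] - c0) < side_lr + 2)) next
        lr[r0 + seq_len(side_lr), c0 + seq_len(side_lr)] <-
          lr[r0 + seq_len(side_lr), c0 + seq_len(side_lr)] | disc
        anchors <- rbind(anchors, c(r0, c0))
        break
      }
    }
    mask <- resize_image(lr * 1L, image_size(canvas, canvas),
                         mode = "nearest")
    list(image = mask + 0.0, mask = mask)
  })
}

#' Deterministic oracle segmenters
#'
#' Stand-ins for trained networks so every pipeline stage can be tested
#' end-to-end without training:
#' \describe{
#'   \item{`"gt_reader"`}{Returns its input clipped to `[0, 1]` as scores.
#'     Feed it the ground truth presented as the image (as
#'     [synth_exact_fit()] produces): the rough stage then yields the
#'     downscaled ground truth and the fine stage the ground-truth crop.}
#'   \item{`"threshold"`}{Scores 1 where intensity exceeds `cut`, else 0.
#'     On noise-free synthetic images with separable intensities this
#'     reproduces the ground truth exactly.}
#' }
#'
#' @param mode `"gt_reader"` or `"threshold"`.
#' @param input_size Expected input size S.
#' @param cut Intensity cut for `"threshold"` (default 0.5).
#' @return A [segmenter()].
#' @export
oracle_segmenter <- function(mode = c("gt_reader", "threshold"),
                             input_size, cut = 0.5) {
  mode <- match.arg(mode)
  fn <- if (mode == "gt_reader") {
    function(img) {
      if (length(dim(img)) == 3) img <- img[, , 1]
      pmin(pmax(img, 0), 1)
    }
  } else {
    function(img) {
      if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
      (img > cut) * 1
    }
  }
  segmenter(fn, input_size = input_size, channels = 1L,
            name = paste0("oracle:", mode))
}
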