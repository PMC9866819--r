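# Segmentation scoring: Dice, IoU, precision, recall, and the
# upscale-to-original-resolution evaluation protocol.

#' Score a predicted mask against ground truth
#'
#' Pixel-overlap metrics from true-positive / false-positive /
#' false-negative counts:
#' \deqn{DSC = 2TP / (2TP + FP + FN)}
#' \deqn{IoU = TP / (TP + FP + FN)}
#' \deqn{precision = TP / (TP + FP), \quad recall = TP / (TP + FN)}
#' When both masks are empty all four scores are 1 (a correctly predicted
#' empty image is a perfect prediction); a ratio whose denominator is zero
#' while the other mask is non-empty scores 0.
#'
#' @param pred,gt Binary matrices of identical shape.
#' @return An object of class `"score_report"`: list with `dsc`, `iou`,
#'   `precision`, `recall`, all in `[0, 1]`.
#' @examples
#' p <- matrix(0L, 4, 4); g <- matrix(0L, 4, 4)
#' p[1, 1:4] <- 1L; g[1, 3:4] <- 1L; g[2, 3:4] <- 1L  # 4 px each, overlap 2
#' score(p, g)  # dsc 0.5, iou 1/3
#' @export
score <- function(pred, gt) {
  pred <- as_binary_mask(pred); gt <- as_binary_mask(gt)
  if (!identical(dim(pred), dim(gt)))
    stop("pred and gt shapes differ")
  tp <- sum(pred == 1L & gt == 1L)
  fp <- sum(pred == 1L & gt == 0L)
  fn <- sum(pred == 0L & gt == 1L)
  ratio <- function(num, den, both_empty_value = 1) {
    if (den == 0) {
      if (tp + fp + fn == 0) both_empty_value else 0
    } else num / den
  }
  structure(list(dsc = ratio(2 * tp, 2 * tp + fp + fn),
                 iou = ratio(tp, tp + fp + fn),
                 precision = if (tp + fp == 0 && tp + fp + fn > 0) 0
                             else ratio(tp, tp + fp),
                 recall = if (tp + fn == 0 && tp + fp + fn > 0) 0
                          else ratio(tp, tp + fn)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score dsc=%.4f iou=%.4f prec=%.4f rec=%.4f>\n",
              x$dsc, x$iou, x$precision, x$recall))
  invisible(x)
}

#' Score a low-resolution prediction at original resolution
#'
#' The evaluation protocol for downscaled-input models: the predicted mask
#' is upscaled (nearest-neighbour) to the original resolution first, and
#' metrics are computed there, so models are compared on the resolution the
#' task actually lives at.
#'
#' @param pred_small Binary matrix at network resolution.
#' @param gt_full Binary matrix at original resolution.
#' @param size An [image_size()]; must match `gt_full`.
#' @return A `"score_report"`, as [score()].
#' @export
score_upscaled <- function(pred_small, gt_full, size = size_of(gt_full)) {
  pred_small <- as_binary_mask(pred_small)
  gt_full <- as_binary_mask(gt_full)
  stopifnot(inherits(size, "image_size"),
            nrow(gt_full) == size$height, ncol(gt_full) == size$width)
  score(resize_image(pred_small, size, mode = "nearest"), gt_full)
}

#' Summarise per-image score reports
#'
#' @param reports List of `"score_report"` objects.
#' @return Data frame with one row per metric: mean and standard deviation.
#' @export
summarize_scores <- function(reports) {
  stopifnot(length(reports) > 0)
  metrics <- c("dsc", "iou", "precision", "recall")
  vals <- sapply(metrics, function(m) vapply(reports, `[[`, numeric(1), m))
  vals <- matrix(vals, nrow = length(reports))
  data.frame(metric = metrics,
             mean = colMeans(vals),
             sd = apply(vals, 2, stats::sd))
}
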