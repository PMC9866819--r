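# Independent oracles and random-case generators used across tests. These
# deliberately avoid the package's own code paths: labeling by scan-order
# flood fill, fusion by literal per-pixel max, resizing by an explicit index
# map, bounding boxes by exhaustive min/max scan.

# flood-fill labeling, scanning pixels in row-major order
flood_fill_labels <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  nxt <- 0L
  info <- NULL
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] != 0 && lab[r, c] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(r, c)); lab[r, c] <- nxt
      mr <- r; mc <- c
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        mr <- min(mr, p[1]); mc <- min(mc, p[2])
        for (k in seq_len(nrow(nb))) {
          rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              mask[rr, cc] != 0 && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            stack[[length(stack) + 1]] <- c(rr, cc)
          }
        }
      }
      info <- rbind(info, c(nxt, mr, mc))
    }
  }
  if (nxt > 0) {  # renumber by (min row, min col)
    ord <- order(info[, 2], info[, 3])
    remap <- integer(nxt); remap[info[ord, 1]] <- seq_len(nxt)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  lab
}

# tightest box over a pixel set, by exhaustive scan (0-based output)
scan_bbox <- function(lab, id) {
  px <- which(lab == id, arr.ind = TRUE)
  bbox(min(px[, 2]) - 1, min(px[, 1]) - 1,
       diff(range(px[, 2])) + 1, diff(range(px[, 1])) + 1)
}

# literal per-pixel max fusion
fuse_oracle <- function(crop_masks, size) {
  out <- matrix(0L, size$height, size$width)
  for (r in seq_len(size$height)) for (c in seq_len(size$width)) {
    v <- 0L
    for (cm in crop_masks) {
      b <- cm$box
      if (r - 1 >= b$top && r - 1 < b$top + b$height &&
          c - 1 >= b$left && c - 1 < b$left + b$width) {
        v <- max(v, cm$mask[r - b$top, c - b$left])
      }
    }
    out[r, c] <- v
  }
  out
}

# nearest-neighbour resize via the explicit map src = floor(dst * n_src / n_dst)
nn_resize_oracle <- function(m, h, w) {
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    out[r, c] <- m[floor((r - 1) * nrow(m) / h) + 1,
                   floor((c - 1) * ncol(m) / w) + 1]
  }
  out
}

random_box <- function(max_side = 200, max_pos = 300) {
  bbox(sample.int(max_pos, 1) - 150L, sample.int(max_pos, 1) - 150L,
       sample.int(max_side, 1), sample.int(max_side, 1))
}

# random multi-blob binary mask (rectangles, may touch/overlap)
random_blob_mask <- function(h, w, n_blobs = 4, max_blob = 12) {
  m <- matrix(0L, h, w)
  for (i in seq_len(n_blobs)) {
    bh <- sample.int(max_blob, 1); bw <- sample.int(max_blob, 1)
    r0 <- sample.int(h - bh + 1, 1); c0 <- sample.int(w - bw + 1, 1)
    m[r0:(r0 + bh - 1), c0:(c0 + bw - 1)] <- 1L
  }
  m
}

expect_bbox_equal <- function(a, b) {
  testthat::expect_identical(
    c(a$left, a$top, a$width, a$height),
    c(b$left, b$top, b$width, b$height))
}
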