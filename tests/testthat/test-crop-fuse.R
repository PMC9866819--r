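test_that("crop copies the exact sub-array", {
  img <- matrix(1:16, 4, 4)
  expect_identical(crop(img, bbox(1, 1, 2, 2)), img[2:3, 2:3])
  expect_identical(crop(img, bbox(0, 0, 4, 4)), img)
  set.seed(301)
  for (i in 1:20) {
    img <- matrix(runif(30 * 40), 30, 40)
    b <- shift_to_image_region(random_box(20, 40), image_size(30, 40))
    cr <- crop(img, b)
    expect_identical(dim(cr), c(b$height, b$width))
    # pixel-by-pixel copy oracle
    for (k in 1:5) {
      r <- sample.int(b$height, 1); c <- sample.int(b$width, 1)
      expect_identical(cr[r, c], img[b$top + r, b$left + c])
    }
  }
  expect_error(crop(matrix(0, 4, 4), bbox(2, 2, 4, 4)), "outside")
})

test_that("crop keeps all channels of multi-channel images", {
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  cr <- crop(img, bbox(1, 2, 4, 5))
  expect_identical(dim(cr), c(5L, 4L, 3L))
  expect_identical(cr[1, 1, 2], img[3, 2, 2])
})

test_that("nearest resize replicates pixels by the index map", {
  m <- matrix(c(1, 0, 0, 0), 2, 2)
  up <- resize_image(m, image_size(4, 4))
  expect_identical(up[1:2, 1:2], matrix(1, 2, 2))
  expect_identical(sum(up), 4)
  img <- matrix(runif(25), 5, 5)
  expect_identical(resize_image(img, image_size(5, 5)), img)
  set.seed(302)
  m3 <- matrix(runif(9), 3, 3)
  expect_equal(resize_image(m3, image_size(5, 5)), nn_resize_oracle(m3, 5, 5))
  m7 <- matrix(runif(7 * 11), 7, 11)
  expect_equal(resize_image(m7, image_size(13, 4)), nn_resize_oracle(m7, 13, 4))
})

test_that("binary masks stay binary under nearest resize; integer type kept", {
  set.seed(303)
  m <- matrix(rbinom(100, 1, 0.4), 10, 10)
  storage.mode(m) <- "integer"
  out <- resize_image(m, image_size(37, 23))
  expect_true(all(out %in% c(0L, 1L)))
  expect_true(is.integer(out))
})

test_that("bilinear resize interpolates and is identity at equal size", {
  ramp <- matrix(rep(seq(0, 1, length.out = 8), each = 8), 8, 8)
  out <- resize_image(ramp, image_size(8, 16), mode = "bilinear")
  expect_identical(dim(out), c(8L, 16L))
  expect_true(all(diff(out[1, ]) >= -1e-12))   # monotone along the ramp
  expect_identical(resize_image(ramp, image_size(8, 8), mode = "bilinear"),
                   ramp)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("binarize uses the >= threshold convention", {
  expect_identical(binarize(matrix(0, 3, 3)), matrix(0L, 3, 3))
  expect_identical(binarize(matrix(1, 3, 3)), matrix(1L, 3, 3))
  s <- matrix(c(0.5, 0.499, 0.501, 0), 2, 2)
  expect_identical(binarize(s), matrix(c(1L, 0L, 1L, 0L), 2, 2))
})

test_that("fuse is a per-pixel OR over placed crops", {
  sz <- image_size(4, 4)
  a <- list(mask = matrix(1L, 2, 2), box = bbox(0, 0, 2, 2))
  b <- list(mask = matrix(1L, 2, 2), box = bbox(1, 1, 2, 2))
  out <- fuse(list(a, b), sz)
  expect_identical(sum(out), 7L)
  expect_identical(fuse(list(), sz), matrix(0L, 4, 4))
  expect_error(fuse(list(list(mask = matrix(1L, 3, 2), box = bbox(0, 0, 2, 2))),
                    sz), "shape")
})

test_that("fusion equals the literal per-pixel max oracle on random placements", {
  set.seed(304)
  sz <- image_size(40, 40)
  for (i in 1:20) {
    crops <- lapply(seq_len(sample(1:6, 1)), function(j) {
      b <- shift_to_image_region(random_box(15, 40), sz)
      list(mask = matrix(rbinom(b$height * b$width, 1, 0.5),
                         b$height, b$width), box = b)
    })
    expect_identical(fuse(crops, sz), fuse_oracle(crops, sz))
  }
})

test_that("fusion is commutative and idempotent", {
  set.seed(305)
  sz <- image_size(32, 32)
  crops <- lapply(1:5, function(j) {
    b <- shift_to_image_region(random_box(12, 32), sz)
    list(mask = matrix(rbinom(b$height * b$width, 1, 0.4),
                       b$height, b$width), box = b)
  })
  base <- fuse(crops, sz)
  expect_identical(fuse(rev(crops), sz), base)
  expect_identical(fuse(crops[sample(5)], sz), base)
  expect_identical(fuse(c(crops, crops[2]), sz), base)
})

test_that("adding a crop never decreases recall", {
  set.seed(306)
  sz <- image_size(32, 32)
  gt <- random_blob_mask(32, 32, 3)
  crops <- lapply(1:6, function(j) {
    b <- shift_to_image_region(random_box(10, 32), sz)
    list(mask = matrix(rbinom(b$height * b$width, 1, 0.4),
                       b$height, b$width), box = b)
  })
  prev <- 0
  for (k in seq_along(crops)) {
    rec <- score(fuse(crops[1:k], sz), gt)$recall
    expect_gte(rec, prev)
    prev <- rec
  }
})

test_that("the two-stage pipeline reproduces ground truth with oracle segmenters", {
  d <- synth_exact_fit(5, input_size = 64, seed = 401)
  gt_seg <- oracle_segmenter("gt_reader", input_size = 64)
  for (p in d) {
    y <- segment_then_segment(p$image, gt_seg, gt_seg, roi_config(64))
    expect_identical(y, p$mask)
  }
  # threshold oracles on the noise-free separable image do the same
  th <- oracle_segmenter("threshold", input_size = 64, cut = 0.5)
  y <- segment_then_segment(d[[1]]$image, th, th, roi_config(64))
  expect_identical(y, d[[1]]$mask)
})

test_that("a blank image yields an all-zero mask", {
  z <- oracle_segmenter("threshold", input_size = 64, cut = 0.5)
  y <- segment_then_segment(matrix(0, 256, 256), z, z, roi_config(64))
  expect_identical(y, matrix(0L, 256, 256))
})

test_that("the pipeline equals a hand-composed sequence of module operations", {
  d <- generate_synthetic(synth_config(canvas = image_size(512, 512),
                                       n_objects = c(2L, 2L),
                                       radius_px = c(10L, 30L),
                                       noise_sd = 0, seed = 402), 3)
  th <- oracle_segmenter("threshold", input_size = 64, cut = 0.5)
  cfg <- roi_config(64)
  for (p in d) {
    got <- segment_then_segment(p$image, th, th, cfg)
    # hand-composed: downscale -> predict -> binarize -> rois -> per-box
    # crop/resize/predict/binarize/resize-back -> fuse
    full <- image_size(512, 512)
    s64 <- image_size(64, 64)
    small <- resize_image(p$image, s64, mode = "nearest")
    rough <- binarize(segmenter_predict(th, small))
    boxes <- extract_rois(rough, full, cfg)
    placed <- lapply(boxes, function(b) {
      piece <- resize_image(crop(p$image, b), s64, mode = "nearest")
      m <- binarize(segmenter_predict(th, piece))
      list(mask = resize_image(m, image_size(b$height, b$width),
                               mode = "nearest"), box = b)
    })
    expect_identical(got, fuse(placed, full))
  }
})

test_that("pipeline output shape always equals the input image shape", {
  th <- oracle_segmenter("threshold", input_size = 64, cut = 0.5)
  img <- matrix(runif(100 * 180), 100, 180)
  y <- segment_then_segment(img, th, th, roi_config(64))
  expect_identical(dim(y), c(100L, 180L))
})

test_that("segmenter contract is enforced", {
  bad <- segmenter(function(img) img * 3, input_size = 8)
  expect_error(segmenter_predict(bad, matrix(0.9, 8, 8)), "0, 1")
  ok <- segmenter(function(img) img * 0 + 0.7, input_size = 8)
  expect_error(segmenter_predict(ok, matrix(0, 9, 9)), "expects")
  expect_equal(segmenter_predict(ok, matrix(0, 8, 8)), matrix(0.7, 8, 8))
})
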