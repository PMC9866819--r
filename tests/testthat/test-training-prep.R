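test_that("gt_crop_regions equals extract_rois on the same full-resolution mask", {
  set.seed(501)
  cfg <- roi_config(64)
  sz <- image_size(180, 180)
  for (i in 1:25) {
    m <- random_blob_mask(180, 180, sample(1:5, 1))
    a <- gt_crop_regions(m, sz, cfg)
    b <- extract_rois(m, sz, cfg)
    expect_length(a, length(b))
    for (j in seq_along(a)) expect_bbox_equal(a[[j]], b[[j]])
  }
  expect_length(gt_crop_regions(matrix(0L, 64, 64), image_size(64, 64), cfg), 0)
})

test_that("jitter with max_jitter 0 is the identity", {
  b <- bbox(10, 20, 30, 40)
  expect_bbox_equal(jitter_box(b, jitter_config(0)), b)
})

test_that("jitter offsets are bounded, independent and reproducible", {
  b <- bbox(100, 100, 50, 60)
  jit <- jitter_config(16)
  set.seed(502)
  draws <- t(replicate(2000, {
    j <- jitter_box(b, jit)
    c(j$left - b$left, j$top - b$top, j$width - b$width, j$height - b$height)
  }))
  expect_true(all(draws >= -16 & draws <= 16))
  # each coordinate perturbed independently: columns not all identical
  expect_gt(mean(draws[, 1] != draws[, 2]), 0.9)
  expect_lt(abs(cor(draws[, 3], draws[, 4])), 0.1)
  set.seed(99); a <- jitter_box(b, jit)
  set.seed(99); b2 <- jitter_box(b, jit)
  expect_bbox_equal(a, b2)
})

test_that("jitter clamps dimensions that would collapse", {
  set.seed(503)
  for (i in 1:200) {
    j <- jitter_box(bbox(5, 5, 2, 2), jitter_config(16))
    expect_gte(j$width, 1L)
    expect_gte(j$height, 1L)
  }
})

test_that("empty ground truth falls back to the whole downscaled image", {
  img <- matrix(runif(128 * 128), 128, 128)
  gt <- matrix(0L, 128, 128)
  s <- sample_training_crop(img, gt, roi_config(64))
  expect_null(s$box)
  expect_identical(s$image, resize_image(img, image_size(64, 64),
                                         mode = "nearest"))
  expect_identical(s$mask, matrix(0L, 64, 64))
})

test_that("an exactly-fitting crop without jitter is the literal sub-image", {
  d <- synth_exact_fit(1, input_size = 64, seed = 504)
  p <- d[[1]]
  s <- sample_training_crop(p$image, p$mask, roi_config(64), jitter_config(0))
  expect_identical(dim(s$image), c(64L, 64L))
  b <- s$box
  expect_identical(b$width, 64L)
  expect_identical(s$image, crop(p$image, b))
  expect_identical(s$mask, crop(p$mask, b))
})

test_that("crop regions are chosen uniformly at random", {
  # three well-separated components; count picks over seeded draws
  img <- matrix(0, 256, 256)
  gt <- matrix(0L, 256, 256)
  gt[21:40, 21:40] <- 1L
  gt[21:40, 161:180] <- 1L
  gt[181:200, 91:110] <- 1L
  img[gt == 1L] <- 1
  cfg <- roi_config(64)
  regions <- gt_crop_regions(gt, image_size(256, 256), cfg)
  expect_length(regions, 3)
  set.seed(505)
  counts <- integer(3)
  for (i in 1:900) {
    s <- sample_training_crop(img, gt, cfg, jitter_config(0))
    hit <- which(vapply(regions, function(r)
      r$left == s$box$left && r$top == s$box$top, logical(1)))
    counts[hit] <- counts[hit] + 1L
  }
  expect_identical(sum(counts), 900L)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("sample_training_crop output shapes and mask binarity hold under jitter", {
  set.seed(506)
  cfg <- roi_config(64)
  d <- generate_synthetic(synth_config(seed = 507), 5)
  for (p in d) {
    s <- sample_training_crop(p$image, p$mask, cfg, jitter_config(16))
    expect_identical(dim(s$image), c(64L, 64L))
    expect_identical(dim(s$mask), c(64L, 64L))
    expect_true(all(s$mask %in% c(0L, 1L)))
  }
})

test_that("augmentation with zero probabilities is the identity", {
  set.seed(508)
  img <- matrix(runif(64 * 64), 64, 64)
  mask <- random_blob_mask(64, 64, 2)
  out <- augment(img, mask, augment_config(affine_prob = 0, hflip_prob = 0))
  expect_identical(out$image, img)
  expect_identical(out$mask, mask)
})

test_that("a horizontal flip reverses column order in both image and mask", {
  set.seed(509)
  img <- matrix(runif(32 * 32), 32, 32)
  mask <- random_blob_mask(32, 32, 2)
  out <- augment(img, mask, augment_config(affine_prob = 0, hflip_prob = 1))
  expect_identical(out$image, img[, 32:1])
  expect_identical(out$mask, mask[, 32:1])
  # flip is an involution
  back <- augment(out$image, out$mask,
                  augment_config(affine_prob = 0, hflip_prob = 1))
  expect_identical(back$image, img)
  expect_identical(back$mask, mask)
})

test_that("affine augmentation is reproducible under a seed and keeps pairs aligned", {
  img <- matrix(runif(64 * 64), 64, 64)
  mask <- matrix(0L, 64, 64); mask[20:40, 25:45] <- 1L
  img[mask == 1L] <- img[mask == 1L] + 2
  cfg <- augment_config(affine_prob = 1, hflip_prob = 0)
  set.seed(510); a <- augment(img, mask, cfg)
  set.seed(510); b <- augment(img, mask, cfg)
  expect_identical(a, b)
  expect_identical(dim(a$image), dim(img))
  expect_true(all(a$mask %in% c(0L, 1L)))
  # transform moved but preserved the object roughly: bright pixels should
  # still coincide with the transformed mask
  expect_gt(mean(a$image[a$mask == 1L]), mean(a$image[a$mask == 0L]))
})

test_that("CT windowing maps the stated closed form", {
  expect_equal(ct_window(matrix(350, 1, 1), 200, 500), matrix(-0.1, 1, 1))
  expect_equal(ct_window(matrix(c(100, 200), 1, 2), 200, 500),
               matrix(-0.6, 1, 2))
  expect_equal(ct_window(matrix(c(500, 900), 1, 2), 200, 500),
               matrix(0.4, 1, 2))
  x <- matrix(runif(100, -500, 1500), 10, 10)
  w <- ct_window(x)
  expect_true(all(w >= -0.6 & w <= 0.4))
  expect_error(ct_window(matrix(0, 1, 1), 300, 300), "hi > lo")
})
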