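# Mixing algebra, augmentation bookkeeping and leakage-free splits.

test_that("mixing is the exact convex combination of signal and noise", {
  s <- small_phantom(1); n <- small_ring_noise(2)
  expect_identical(mix_images(s, n, 0), s)
  expect_identical(mix_images(s, n, 1), n)
  m <- mix_images(s, n, 0.5)
  expect_equal(m, 0.5 * n + 0.5 * s)
  expect_error(mix_images(s, n, 1.2), "\\[0, 1\\]")
  expect_error(mix_images(s, n[1:10, 1:10], 0.5), "identical shapes")

  # affine property: mix(s, n, w) - mix(s, n, 0) == w * (n - s)
  for (w in c(0.25, 0.6, 0.9))
    expect_equal(mix_images(s, n, w) - s, w * (n - s), tolerance = 1e-12)
})

test_that("augmentation returns factor-many recorded variants", {
  img <- small_phantom(3, grid = 32)
  cfg <- augmentation_config(factor = 4, seed = 5)
  out <- augment_image(img, cfg)
  expect_length(out, 4)
  expect_identical(out[[1]], structure(img, aug_ops = "identity"))
  expect_true(all(vapply(out, function(m) !is.null(attr(m, "aug_ops")),
                         logical(1))))
  # deterministic per seed
  expect_identical(augment_image(img, cfg), out)
  # noise-only ops rejected for signal images
  bad <- augmentation_config(factor = 2, ops = c("flip", "white_noise"))
  expect_error(augment_image(img, bad, is_noise = FALSE), "noise images")
  expect_silent(augment_image(img, bad, is_noise = TRUE))
})

test_that("flip is an involution and 90-degree rotation matches re-indexing", {
  img <- unclass(small_phantom(7, grid = 32))
  attr(img, "pixel_spacing") <- NULL
  flipped <- img[, ncol(img):1]
  expect_identical(flipped[, ncol(img):1], img)

  # oracle: direct array re-indexing for a quarter turn
  r90 <- rotate_image(img, 90)
  oracle <- t(img)[nrow(img):1, ]
  expect_equal(r90, oracle)
  expect_equal(rotate_image(rotate_image(img, 180), 180), img)
  # arbitrary-angle rotation preserves shape and range
  r33 <- rotate_image(img, 33)
  expect_equal(dim(r33), dim(img))
  expect_true(all(r33 >= -1e-9 & r33 <= 1 + 1e-9))
})

test_that("ten-fold augmentation of 550 sources yields 5500 images", {
  set.seed(1)
  sources <- lapply(1:550, function(i) matrix(runif(32 * 32), 32))
  cfg <- augmentation_config(factor = 10, ops = c("flip", "brightness_contrast"),
                             seed = 2)
  total <- 0L
  for (i in seq_along(sources))
    total <- total + length(augment_image(sources[[i]], cfg))
  expect_identical(total, 5500L)
})

test_that("dataset splits are leakage-free and w values respect their ranges", {
  pool <- fixture_pool()
  ds <- build_dataset(pool$signals[1:20], pool$noises[1:20],
                      split_spec(8, 3, 3), augmentation_config(3),
                      w_range = c(0.1, 0.9), seed = 4)
  expect_length(ds$train, 24)          # factor x train sources exactly
  expect_length(ds$val, 9)             # 3 signals x 3 noise levels
  expect_length(ds$test, 9)

  man <- ds$manifest
  for (p in c("train", "val", "test")) {
    other <- setdiff(c("train", "val", "test"), p)
    expect_length(intersect(man$signal_src[man$partition == p],
                            man$signal_src[man$partition %in% other]), 0)
    expect_length(intersect(man$noise_src[man$partition == p],
                            man$noise_src[man$partition %in% other]), 0)
  }
  wt <- man$w[man$partition == "train"]
  expect_true(all(wt >= 0.1 & wt <= 0.9))
  expect_setequal(unique(man$w[man$partition == "test"]), c(0.3, 0.5, 0.7))

  # every triplet satisfies the mixing invariant
  tr <- ds$train[[5]]
  expect_equal(tr$mixed, tr$w * tr$noise + (1 - tr$w) * tr$signal)

  # degenerate w range pins all training noise levels
  ds2 <- build_dataset(pool$signals[1:6], pool$noises[1:6], split_spec(2, 2, 2),
                       augmentation_config(1), w_range = c(0.5, 0.5), seed = 1)
  expect_true(all(vapply(ds2$train, function(t) t$w, numeric(1)) == 0.5))

  expect_error(build_dataset(pool$signals[1:3], pool$noises[1:3],
                             split_spec(2, 1, 1), augmentation_config(1)),
               "split requests")
})
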