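# Quality metrics: VIF, PSNR, CNR and pairwise variability.

test_that("vif is exactly 1 on identical non-constant images", {
  set.seed(10)
  for (i in 1:20) {
    x <- matrix(runif(64 * 64), 64)
    expect_equal(vif(x, x), 1, tolerance = 1e-12)
  }
  expect_error(vif(matrix(0.5, 64, 64), matrix(0.5, 64, 64)), "constant")
})

test_that("vif matches a hand evaluation on a single 4x4 block", {
  set.seed(3)
  gt <- matrix(runif(16), 4)
  p <- gt + matrix(rnorm(16, 0, 0.1), 4)
  cfg <- vif_config(n_scales = 1, block = 4, sigma_n_sq = 2)
  # oracle: scalar arithmetic on the block statistics
  vg <- mean(gt^2) - mean(gt)^2
  vp <- mean(p^2) - mean(p)^2
  cv <- mean(gt * p) - mean(gt) * mean(p)
  g <- cv / max(vg, 1e-10)
  sv2 <- max(vp - g * cv, 0)
  oracle <- log10(1 + g^2 * vg / (sv2 + 2)) / log10(1 + vg / 2)
  expect_equal(vif(gt, p, cfg), oracle, tolerance = 1e-12)
})

test_that("vif decreases monotonically with the noise level", {
  for (i in 1:10) {
    s <- small_phantom(100 + i)
    n <- small_ring_noise(200 + i)
    vals <- vapply(c(0.3, 0.5, 0.7),
                   function(w) vif(s, mix_images(s, n, w)), numeric(1))
    expect_true(all(diff(vals) < 0),
                label = sprintf("vif declining over w for pair %d", i))
    expect_true(all(vals > 0 & vals <= 1))
  }
})

test_that("vif is invariant to permuting blocks within a scale", {
  set.seed(4)
  x <- matrix(runif(32 * 32), 32)
  y <- x + matrix(rnorm(32 * 32, 0, 0.05), 32)
  cfg <- vif_config(n_scales = 1, block = 8)
  v1 <- vif(x, y, cfg)
  # swap two 8x8 blocks coherently in both images
  xs <- x; ys <- y
  xs[1:8, 1:8] <- x[9:16, 9:16]; xs[9:16, 9:16] <- x[1:8, 1:8]
  ys[1:8, 1:8] <- y[9:16, 9:16]; ys[9:16, 9:16] <- y[1:8, 1:8]
  expect_equal(vif(xs, ys, cfg), v1, tolerance = 1e-12)
})

test_that("psnr follows its closed form with an infinity sentinel", {
  x <- matrix(runif(100), 10)
  expect_identical(psnr(x, x), Inf)
  y <- x + 0.1            # MSE = 0.01 on unit range -> 20 dB
  expect_equal(psnr(x, y), 20, tolerance = 1e-9)
  set.seed(2)
  p <- matrix(runif(100), 10)
  expect_equal(psnr(x, p), 10 * log10(1 / mean((x - p)^2)), tolerance = 1e-9)
})

test_that("cnr matches hand arithmetic and is translation invariant", {
  img <- matrix(0.2, 40, 40)
  d <- 0.1 * sqrt(99 / 100)          # alternating offsets -> unbiased sd 0.1
  img[1:10, 1:10] <- 0.2 + rep(c(-d, d), 50)
  img[20:26, 20:26] <- 0.8
  spec <- roi_spec(roi = c(20, 20, 7, 7), background = c(1, 1, 10, 10))
  expect_equal(cnr(img, spec), 6, tolerance = 1e-9)
  expect_equal(cnr(img + 0.13, spec), cnr(img, spec), tolerance = 1e-9)

  # identical statistics in both regions give zero contrast
  flatish <- matrix(0.2, 40, 40)
  flatish[1:10, 1:10] <- 0.2 + rep(c(-d, d), 50)
  flatish[20:26, 20:26] <- 0.2 + rep(c(-d, d), length.out = 49)
  expect_lt(abs(cnr(flatish, spec)), 0.05)

  expect_error(roi_spec(c(1, 1, 10, 10), c(5, 5, 10, 10)), "overlap")
  expect_error(cnr(matrix(0.5, 40, 40), spec), "zero variance")
})

test_that("pairwise variability summarizes frame stacks faithfully", {
  f <- small_phantom(5, grid = 32)
  same <- rep(list(f), 6)
  r <- pairwise_variability(same, max_pairs = 100)
  expect_equal(unname(r$ssim["mean"]), 1, tolerance = 1e-9)
  expect_equal(r$n_pairs, 15)        # C(6, 2)

  set.seed(12)
  frames <- lapply(1:10, function(i) f + matrix(rnorm(32 * 32, 0, 0.1), 32))
  r10 <- pairwise_variability(frames, max_pairs = 45)
  expect_equal(r10$n_pairs, 45)      # exactly N(N-1)/2

  # seeded subsample stays within Monte-Carlo error of the exhaustive mean
  frames30 <- lapply(1:30, function(i) f + matrix(rnorm(32 * 32, 0, 0.1), 32))
  all_pairs <- pairwise_variability(frames30, max_pairs = 10000)
  sub <- pairwise_variability(frames30, max_pairs = 120, seed = 2)
  se <- all_pairs$ssim["sd"] / sqrt(120)
  expect_lt(abs(sub$ssim["mean"] - all_pairs$ssim["mean"]), 4 * se + 1e-3)
  expect_error(pairwise_variability(list(f)), "at least 2")
})

test_that("quality reports carry per-image metrics with ROI provenance", {
  s <- small_phantom(6); n <- small_ring_noise(6)
  m <- mix_images(s, n, 0.5)
  roi <- auto_roi(s)
  rep <- quality_report(list(s), list(m), list(roi))
  expect_s3_class(rep, "quality_report")
  expect_true(rep$vif < 1 && rep$vif > 0)
  expect_true(is.finite(rep$cnr))
  expect_match(rep$roi, ",")
  f <- tempfile(fileext = ".csv")
  write_quality_report(rep, f)
  expect_equal(nrow(read.csv(f)), 1)
  unlink(f)
})
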