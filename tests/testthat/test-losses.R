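# Loss-evaluation modules: values, gradients and invariants.

test_that("every loss kind is zero on identical inputs and positive otherwise", {
  set.seed(1)
  x <- matrix(runif(64 * 64), 64)
  y <- x; y[10, 10] <- y[10, 10] + 0.5
  for (kind in c("mse", "mae", "ssim", "ms_ssim", "perceptual")) {
    sp <- loss_spec(kind, ms_scales = 2)
    expect_equal(as.numeric(loss_value(sp, x, x)), 0, tolerance = 1e-6,
                 label = paste(kind, "self-distance"))
    expect_gt(as.numeric(loss_value(sp, y, x)), 1e-8)
  }
})

test_that("mse matches hand arithmetic on a 2x2 example", {
  a <- matrix(0, 2, 2)
  b <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(as.numeric(loss_value(loss_spec("mse"), a, b)), 0.25)
  expect_equal(as.numeric(loss_value(loss_spec("mae"), a, b)), 0.25)
})

test_that("perceptual loss flags a bright ring and ignores tap order", {
  n <- small_ring_noise(4)
  zero <- array(0, dim(n))
  sp <- loss_spec("perceptual")
  v <- as.numeric(loss_value(sp, zero, n))
  expect_gt(v, 0)
  # averaging over taps is symmetric under permutation
  sp_rev <- loss_spec("perceptual", layer_taps = c(3, 1, 2))
  sp_fwd <- loss_spec("perceptual", layer_taps = c(1, 2, 3))
  expect_equal(as.numeric(loss_value(sp_rev, zero, n)),
               as.numeric(loss_value(sp_fwd, zero, n)), tolerance = 1e-10)
  # missing pretrained weights are a hard error
  expect_error(loss_spec("perceptual", extractor = "vgg19_style",
                         weights_source = "pretrained_file"),
               "weights file")
})

test_that("ssim agrees with its definition and declines with corruption", {
  s <- small_phantom(2)
  expect_equal(ssim(s, s), 1, tolerance = 1e-12)
  n <- small_ring_noise(3)
  v1 <- ssim(s, mix_images(s, n, 0.3))
  v2 <- ssim(s, mix_images(s, n, 0.7))
  expect_true(v1 > v2)
  expect_true(v2 > 0)
  expect_equal(ms_ssim(s, s, scales = 2), 1, tolerance = 1e-9)
})

test_that("analytic loss gradients match central differences", {
  set.seed(6)
  tgt <- small_ring_noise(6, grid = 32)
  p0 <- 0.6 * tgt + matrix(rnorm(32 * 32, 0, 0.08), 32)
  tols <- c(mse = 1e-6, ssim = 1e-5, perceptual = 0.1)  # perceptual is float32
  for (kind in names(tols)) {
    sp <- loss_spec(kind)
    expect_grad_matches(function(p, grad = FALSE) loss_value(sp, p, tgt, grad),
                        p0, npix = 4, tol = tols[[kind]])
  }
  # MS-SSIM on a larger fixture so two scales fit the analysis window
  tgt2 <- small_ring_noise(7, grid = 64)
  p2 <- 0.5 * tgt2 + matrix(rnorm(64 * 64, 0, 0.05), 64)
  sp2 <- loss_spec("ms_ssim", ms_scales = 2)
  expect_grad_matches(function(p, grad = FALSE) loss_value(sp2, p, tgt2, grad),
                      p2, npix = 3, tol = 0.05)
})

test_that("ms-ssim rejects images smaller than its coarsest scale", {
  x <- matrix(runif(32 * 32), 32)
  expect_error(loss_value(loss_spec("ms_ssim", ms_scales = 5), x, x),
               "smaller than")
})

test_that("shape mismatches are rejected for every loss kind", {
  a <- matrix(0, 8, 8); b <- matrix(0, 9, 9)
  expect_error(loss_value(loss_spec("mse"), a, b), "identical shapes")
})
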