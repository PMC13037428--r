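# Residual-learning training loop and the subtract-and-restore path.

test_that("bcr is an affine-invariant remap onto the unit interval", {
  set.seed(1)
  x <- matrix(runif(64 * 64), 64)
  expect_equal(bcr(3 * x + 0.2), bcr(x), tolerance = 1e-12)
  b <- bcr(x)
  expect_true(all(b >= 0 & b <= 1))
  expect_true(all(bcr(matrix(0.7, 10, 10)) == 0))

  # ramp image: the percentile endpoints map to 0 and 1
  ramp <- matrix(seq(0, 1, length.out = 10000), 100)
  br <- bcr(ramp)
  q <- stats::quantile(ramp, c(0.01, 0.99), names = FALSE)
  expect_lt(abs(br[which.min(abs(ramp - q[1]))]), 1e-3)
  expect_lt(abs(br[which.min(abs(ramp - q[2]))] - 1), 1e-3)
})

test_that("the zero predictor is conservative and the residual identity holds", {
  s <- small_phantom(1); n <- small_ring_noise(1)
  mixed <- mix_images(s, n, 0.6)
  r <- denoise(function(img) array(0, dim(img)), mixed)
  expect_identical(r$restored_raw, mixed)
  expect_equal(psnr(s, r$restored_raw), psnr(s, mixed))  # no silent improvement
  expect_equal(r$restored_raw + r$predicted_noise, r$noisy, tolerance = 1e-12)
})

test_that("an oracle noise predictor restores the scaled clean signal", {
  for (i in 1:10) {
    s <- small_phantom(300 + i); n <- small_ring_noise(400 + i)
    w <- 0.3 + 0.05 * i
    mixed <- mix_images(s, n, w)
    r <- denoise(function(img) w * n, mixed)
    # algebra of the mixing formula, verified numerically
    expect_equal(r$restored_raw, (1 - w) * s, tolerance = 1e-12)
    expect_equal(r$restored_raw + r$predicted_noise, r$noisy, tolerance = 1e-12)
    # BCR maps the scaled signal back onto the normalized signal
    expect_gte(ssim(bcr(s), bcr(r$restored_raw)), 0.999)
  }
})

test_that("training is seeded, loss decreases, and guards fire", {
  pool <- fixture_pool()
  ds <- build_dataset(pool$signals[1:12], pool$noises[1:12], split_spec(8, 2, 2),
                      augmentation_config(2), seed = 3)
  cfg <- network_config(depth = 2, base_channels = 8, input_size = 64)
  ctl <- trainer_config(epochs = 6, batch_size = 8, seed = 5)
  f1 <- fit_denoiser(ds$train, ds$val, network = cfg, loss = loss_spec("mse"),
                     control = ctl)
  f2 <- fit_denoiser(ds$train, ds$val, network = cfg, loss = loss_spec("mse"),
                     control = ctl)
  expect_identical(f1$history, f2$history)          # determinism contract
  expect_lt(f1$history$train_loss[6], f1$history$train_loss[1])
  expect_lte(min(f1$history$val_loss), f1$history$val_loss[1])
  expect_error(trainer_config(epochs = 0), "epochs")

  # fitted-model methods
  expect_output(print(f1), "Residual-noise denoiser")
  expect_s3_class(f1$history, "data.frame")
  res <- predict(f1, ds$test[[1]])
  expect_s3_class(res, "oa_denoised")
  expect_equal(res$restored_raw, res$noisy - res$predicted_noise)
  pn <- residuals(f1, ds$test[[1]])
  expect_equal(pn, res$predicted_noise)
  expect_true(length(coef(f1)) > 10)
})

test_that("a fitted denoiser survives disk round trips including weights", {
  pool <- fixture_pool()
  ds <- build_dataset(pool$signals[1:6], pool$noises[1:6], split_spec(4, 1, 1),
                      augmentation_config(1), seed = 2)
  f <- fit_denoiser(ds$train, ds$val,
                    network = network_config(depth = 2, base_channels = 4,
                                             se_reduction = 2, input_size = 64),
                    loss = loss_spec("mse"),
                    control = trainer_config(epochs = 2, seed = 1))
  x <- ds$test[[1]]$mixed
  y1 <- predict(f, x)$predicted_noise
  path <- tempfile(fileext = ".rds")
  save_denoiser(f, path)
  g <- load_denoiser(path)
  expect_equal(predict(g, x)$predicted_noise, y1, tolerance = 1e-6)
  side <- jsonlite::read_json(sub("\\.rds$", ".json", path))
  expect_equal(side$network$depth, 2)
  unlink(c(path, sub("\\.rds$", ".json", path)))
})
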