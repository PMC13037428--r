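# Synthetic phantom and ring-artifact generation.

test_that("phantom generation is deterministic and respects the vessel count", {
  cfg <- phantom_config(grid_size = 64, n_vessels = 5, seed = 42)
  a <- make_phantom(cfg)
  b <- make_phantom(cfg)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))

  # oracle: threshold above the body background, count connected components
  lab <- EBImage::bwlabel(a > cfg$body_level + 0.05)
  expect_equal(max(lab), 5)

  # degenerate case: no vessels -> body ellipse only, max equals background
  flat <- make_phantom(phantom_config(grid_size = 64, n_vessels = 0, seed = 1))
  expect_equal(max(flat), phantom_config(grid_size = 64)$body_level)
})

test_that("phantom config rejects invalid geometry", {
  expect_error(phantom_config(grid_size = 16), "32")
  expect_error(phantom_config(vessel_radius_range = c(20, 30)),
               "larger than body axis")
})

test_that("spike injection places the configured number of isolated pulses", {
  g <- fixture_geometry()
  s0 <- inject_spikes(g, 256, spike_noise_config(n_spikes = 0, seed = 1))
  expect_true(all(s0$samples == 0))

  s3 <- inject_spikes(g, 256, spike_noise_config(n_spikes = 3, spike_width = 1,
                                                 seed = 7))
  expect_equal(sum(s3$samples != 0), 3)        # oracle: count nonzeros

  cfg <- spike_noise_config(n_spikes = 10, spike_width = 3,
                            amplitude_range = c(0.5, 1.5), seed = 2)
  s <- inject_spikes(g, 512, cfg)
  nz <- s$samples[s$samples != 0]
  expect_true(all(nz >= 0.5 & nz <= 1.5))
  expect_equal(length(nz), 10 * 3)

  expect_error(inject_spikes(g, 2, spike_noise_config(spike_width = 3)),
               "exceed")
  expect_error(inject_spikes(array_geometry(n_elements = 2), 4,
                             spike_noise_config(n_spikes = 100, spike_width = 1)),
               "exceeds")
})

test_that("backprojection maps a single spike onto the predicted circle", {
  g <- fixture_geometry()
  n_time <- 2048
  # spike at detector 5, time index t0 (0-based delay t0 - 1)
  t0 <- 1100
  s <- matrix(0, g$n_elements, n_time)
  s[5, t0] <- 1
  sino <- structure(list(samples = s, geometry = g), class = "sinogram")
  img <- backproject(sino, grid_size = 128, fov = 40)

  radius_mm <- (t0 - 1) / g$sampling_rate * g$speed_of_sound
  pos <- oadenoise:::detector_positions(g)[5, ]
  co <- oadenoise:::pixel_coords(128, 40)
  X <- matrix(co$x, 128, 128, byrow = TRUE)
  Y <- matrix(co$y, 128, 128)
  dist <- sqrt((X - pos[1])^2 + (Y - pos[2])^2)
  bright <- which(img >= max(img) * 0.999)
  # oracle: brightest pixels sit within one pixel of the time-of-flight circle
  expect_true(all(abs(dist[bright] - radius_mm) <= co$spacing))
})

test_that("backprojection is linear and zero-preserving", {
  g <- array_geometry(n_elements = 16)
  zero <- structure(list(samples = matrix(0, 16, 64), geometry = g),
                    class = "sinogram")
  expect_true(all(backproject(zero, 32, 40) == 0))

  set.seed(5)
  for (i in 1:5) {
    a <- structure(list(samples = matrix(rnorm(16 * 64), 16), geometry = g),
                   class = "sinogram")
    b <- structure(list(samples = matrix(rnorm(16 * 64), 16), geometry = g),
                   class = "sinogram")
    ab <- a; ab$samples <- a$samples + b$samples
    lhs <- backproject(a, 32, 40) + backproject(b, 32, 40)
    rhs <- backproject(ab, 32, 40)
    expect_lt(max(abs(lhs - rhs)), 1e-6)
  }
})

test_that("ring-noise images are normalized, reproducible and structured", {
  g <- fixture_geometry()
  cfg <- spike_noise_config(n_spikes = 8, seed = 3)
  a <- make_ring_noise(g, cfg, grid_size = 64)
  expect_identical(a, make_ring_noise(g, cfg, grid_size = 64))
  expect_true(all(a >= 0 & a <= 1))

  # degenerate config collapses to the all-zero image
  quiet <- make_ring_noise(g, spike_noise_config(n_spikes = 0,
                                                 white_noise_sigma = 0,
                                                 salt_pepper_fraction = 0),
                           grid_size = 64)
  expect_true(all(quiet == 0))

  # structured spatial correlation: lag-2 autocorrelation beats white noise
  lag2 <- function(m) {
    v <- m - mean(m)
    sum(v[, 1:(ncol(v) - 2)] * v[, 3:ncol(v)]) / sum(v^2)
  }
  set.seed(11)
  white <- matrix(rnorm(64 * 64, mean(a), stats::sd(a)), 64)
  expect_gt(lag2(a), lag2(white))
})

test_that("single-spike ring noise peaks at the time-of-flight radius", {
  g <- fixture_geometry()
  cfg <- spike_noise_config(n_spikes = 1, spike_width = 1,
                            white_noise_sigma = 0, salt_pepper_fraction = 0,
                            seed = 9)
  n_time <- 2048
  sino <- inject_spikes(g, n_time, cfg)
  hit <- which(sino$samples != 0, arr.ind = TRUE)[1, ]
  img <- make_ring_noise(g, cfg, grid_size = 128, n_time = n_time)

  pos <- oadenoise:::detector_positions(g)[hit[1], ]
  co <- oadenoise:::pixel_coords(128, 40)
  X <- matrix(co$x, 128, 128, byrow = TRUE)
  Y <- matrix(co$y, 128, 128)
  dist <- sqrt((X - pos[1])^2 + (Y - pos[2])^2)
  radius_mm <- (hit[2] - 1) / g$sampling_rate * g$speed_of_sound

  # oracle: radial binning about the generating detector
  bins <- cut(as.vector(dist), breaks = seq(0, max(dist) + 1, by = co$spacing))
  prof <- tapply(as.vector(img), bins, mean)
  peak_r <- (which.max(prof) - 0.5) * co$spacing
  expect_lt(abs(peak_r - radius_mm), 2 * co$spacing)
})

test_that("sinogram round-trips through RDS storage", {
  g <- array_geometry(n_elements = 8)
  s <- inject_spikes(g, 32, spike_noise_config(n_spikes = 2, spike_width = 1))
  f <- tempfile(fileext = ".rds")
  save_sinogram(s, f)
  s2 <- load_sinogram(f)
  expect_equal(s2$samples, s$samples)
  expect_equal(s2$geometry$n_elements, 8)
  unlink(f)
})
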