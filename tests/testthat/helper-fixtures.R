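# Shared fixtures.  Simulated images are generated once per session and
# reused across test files; everything is a pure function of fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

fixture_geometry <- function() array_geometry(n_elements = 64, radius = 40)

# pool of clean phantoms and ring-noise images (64x64), generated lazily
fixture_pool <- function(n_signals = 248, n_noises = 248, grid = 64) {
  key <- sprintf("pool_%d_%d_%d", n_signals, n_noises, grid)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  g <- fixture_geometry()
  pool <- list(
    signals = lapply(seq_len(n_signals), function(i)
      make_phantom(phantom_config(grid_size = grid, seed = i))),
    noises = lapply(seq_len(n_noises), function(i)
      make_ring_noise(g, spike_noise_config(n_spikes = 12, spike_width = 2,
                                            seed = 1000 + i),
                      grid_size = grid))
  )
  .fixture_env[[key]] <- pool
  pool
}

small_phantom <- function(seed = 1, grid = 64, n_vessels = 5)
  make_phantom(phantom_config(grid_size = grid, n_vessels = n_vessels,
                              seed = seed))

small_ring_noise <- function(seed = 1, grid = 64)
  make_ring_noise(fixture_geometry(),
                  spike_noise_config(n_spikes = 12, spike_width = 2, seed = seed),
                  grid_size = grid)

# numeric directional derivative check helper: compares the analytic
# gradient of fn (returning loss with "gradient" attr) against central
# differences at a handful of pixels
expect_grad_matches <- function(loss_fn, p, npix = 5, eps = 1e-4,
                                tol = 5e-2, seed = 99) {
  v <- loss_fn(p, grad = TRUE)
  g <- attr(v, "gradient")[[1]]
  set.seed(seed)
  idx <- cbind(sample(nrow(p), npix, replace = TRUE),
               sample(ncol(p), npix, replace = TRUE))
  for (i in seq_len(npix)) {
    pp <- p; pp[idx[i, 1], idx[i, 2]] <- pp[idx[i, 1], idx[i, 2]] + eps
    pm <- p; pm[idx[i, 1], idx[i, 2]] <- pm[idx[i, 1], idx[i, 2]] - eps
    num <- (as.numeric(loss_fn(pp, grad = FALSE)) -
              as.numeric(loss_fn(pm, grad = FALSE))) / (2 * eps)
    ana <- g[idx[i, 1], idx[i, 2]]
    expect_equal(ana, num, tolerance = tol,
                 label = sprintf("analytic gradient at pixel (%d,%d)",
                                 idx[i, 1], idx[i, 2]))
  }
}
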