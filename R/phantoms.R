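# Synthetic anatomy phantoms and structured ring-artifact noise.
#
# Full-ring optoacoustic systems reconstruct cross-sectional images in which
# a localized parasitic spike in the sinogram (one detector, one time sample,
# e.g. from electromagnetic interference) backprojects into a circular arc
# centered on that detector.  This module generates (a) clean vessel-in-tissue
# phantoms standing in for laser-acquired reference anatomy and (b) pure
# noise-artifact images obtained by planting spikes in an empty sinogram and
# reconstructing them with a delay-and-sum backprojector, plus stochastic
# white and salt-and-pepper components.

#' Phantom generation settings
#'
#' @param grid_size image side length in pixels (square grid), at least 32.
#' @param fov field of view in mm covered by the grid.
#' @param body_axes semi-axes (mm) of the elliptical tissue body.
#' @param body_level background intensity of the body (dimensionless).
#' @param n_vessels number of bright vessel-like disk inclusions.
#' @param vessel_radius_range disk radius interval in mm.
#' @param vessel_intensity_range disk intensity interval; must exceed
#'   `body_level` for inclusions to read as bright vessels.
#' @param seed integer seed; the phantom is a pure function of this config.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_size = 128, fov = 40,
                           body_axes = c(14, 11), body_level = 0.25,
                           n_vessels = 6, vessel_radius_range = c(0.6, 1.6),
                           vessel_intensity_range = c(0.6, 1), seed = 1) {
  if (!is.numeric(grid_size) || grid_size < 32 || grid_size != round(grid_size))
    stopf("grid_size must be an integer >= 32")
  if (n_vessels < 0) stopf("n_vessels must be >= 0")
  if (diff(range(vessel_radius_range)) < 0 || any(vessel_radius_range <= 0))
    stopf("vessel_radius_range must be a nonempty positive interval")
  if (max(vessel_radius_range) >= min(body_axes))
    stopf("vessel radius larger than body axis")
  if (fov <= 0) stopf("fov must be positive")
  structure(list(grid_size = as.integer(grid_size), fov = fov,
                 body_axes = body_axes, body_level = body_level,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius_range = sort(vessel_radius_range),
                 vessel_intensity_range = sort(vessel_intensity_range),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# physical pixel-center coordinates; image center = array center,
# x to the right (columns), y downward (rows)
pixel_coords <- function(grid_size, fov) {
  spacing <- fov / grid_size
  u <- (seq_len(grid_size) - 1 - (grid_size - 1) / 2) * spacing
  list(x = u, y = u, spacing = spacing)
}

#' Generate a clean anatomy-like phantom image
#'
#' Renders a smooth elliptical tissue body with `n_vessels` non-overlapping
#' bright disks fully inside the body.  Output values lie in `[0, 1]`; the
#' body background sits at `config$body_level` so that with zero vessels the
#' image maximum equals the background level.  Identical configs (including
#' the seed) give bitwise-identical images.
#'
#' @param config a [phantom_config()].
#' @return numeric matrix `grid_size x grid_size` with a `pixel_spacing`
#'   attribute (mm per pixel).
#' @export
make_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  g <- config$grid_size
  co <- pixel_coords(g, config$fov)
  a <- config$body_axes[1]; b <- config$body_axes[2]
  X <- matrix(co$x, g, g, byrow = TRUE)
  Y <- matrix(co$y, g, g)
  e <- sqrt((X / a)^2 + (Y / b)^2)
  img <- config$body_level * clip01((1 - e) / 0.06)  # soft rim over ~6% of e
  if (config$n_vessels > 0) {
    centers <- with_seed(config$seed, {
      out <- matrix(NA_real_, 0, 3)  # cx, cy, r
      tries <- 0
      while (nrow(out) < config$n_vessels && tries < 10000) {
        tries <- tries + 1
        r <- runif(1, config$vessel_radius_range[1], config$vessel_radius_range[2])
        # sample inside the shrunken ellipse so the disk stays within the body
        th <- runif(1, 0, 2 * pi); u <- sqrt(runif(1)) * 0.85
        cx <- u * (a - r - 2 * co$spacing) * cos(th)
        cy <- u * (b - r - 2 * co$spacing) * sin(th)
        ok <- TRUE
        if (nrow(out) > 0) {
          d <- sqrt((out[, 1] - cx)^2 + (out[, 2] - cy)^2)
          ok <- all(d > out[, 3] + r + 2 * co$spacing)
        }
        if (ok) out <- rbind(out, c(cx, cy, r))
      }
      if (nrow(out) < config$n_vessels)
        stopf("could not place %d non-overlapping vessels; reduce n_vessels or radii",
              config$n_vessels)
      out
    })
    intens <- with_seed(config$seed + 1L,
                        runif(config$n_vessels, config$vessel_intensity_range[1],
                              config$vessel_intensity_range[2]))
    for (i in seq_len(config$n_vessels)) {
      d <- sqrt((X - centers[i, 1])^2 + (Y - centers[i, 2])^2)
      disk <- intens[i] * clip01((centers[i, 3] - d) / co$spacing + 0.5)
      img <- pmax(img, disk)
    }
  }
  attr(img, "pixel_spacing") <- co$spacing
  img
}

#' Circular transducer-array geometry
#'
#' Metadata describing the detection array used for sinogram synthesis and
#' backprojection.  The default is a single full 360-degree ring; two-arc
#' layouts (as in full-ring systems built from a pair of arcs) are supported
#' through `n_arcs` and `angular_coverage`.
#'
#' @param n_elements number of detection elements (> 0).
#' @param radius array radius in mm (> 0).
#' @param angular_coverage degrees covered per arc, in (0, 360].
#' @param n_arcs number of arcs the elements are split across.
#' @param sampling_rate temporal sampling rate in samples per second.
#' @param speed_of_sound in mm per second.
#' @return object of class `array_geometry`.
#' @export
array_geometry <- function(n_elements = 64, radius = 40,
                           angular_coverage = 360, n_arcs = 1,
                           sampling_rate = 40e6, speed_of_sound = 1.5e6) {
  if (n_elements <= 0) stopf("n_elements must be > 0")
  if (radius <= 0) stopf("radius must be > 0")
  if (angular_coverage <= 0 || angular_coverage > 360)
    stopf("angular_coverage must be in (0, 360]")
  structure(list(n_elements = as.integer(n_elements), radius = radius,
                 angular_coverage = angular_coverage, n_arcs = as.integer(n_arcs),
                 sampling_rate = sampling_rate, speed_of_sound = speed_of_sound),
            class = "array_geometry")
}

# detector positions (mm), n_elements x 2 (x, y)
detector_positions <- function(geom) {
  n <- geom$n_elements; k <- geom$n_arcs
  per <- n %/% k
  ang <- numeric(0)
  for (j in seq_len(k)) {
    m <- if (j == k) n - per * (k - 1) else per
    base <- (j - 1) * 360 / k
    if (geom$angular_coverage >= 360 && k == 1) {
      ang <- c(ang, (seq_len(m) - 1) / m * 360)
    } else {
      ang <- c(ang, base + seq(-geom$angular_coverage / 2,
                               geom$angular_coverage / 2, length.out = m))
    }
  }
  th <- ang * pi / 180
  cbind(x = geom$radius * cos(th), y = geom$radius * sin(th))
}

#' Spike-noise settings for structured artifact synthesis
#'
#' Parasitic spikes are modeled as boxcar pulses of `spike_width` time
#' samples planted at seeded random (detector, time) positions; the spike
#' density and amplitude statistics of real interference are not
#' characterized, so these defaults are chosen for visual similarity to
#' measured ring-artifact images and are fully configurable.
#'
#' @param n_spikes number of spikes (>= 0).
#' @param amplitude_range interval amplitudes are drawn from.
#' @param spike_width boxcar width in time samples.
#' @param white_noise_sigma std. dev. of additive white noise on the
#'   normalized reconstructed image.
#' @param salt_pepper_fraction fraction of pixels replaced by 0 or 1.
#' @param seed integer seed.
#' @export
spike_noise_config <- function(n_spikes = 25, amplitude_range = c(0.5, 1.5),
                               spike_width = 3, white_noise_sigma = 0.04,
                               salt_pepper_fraction = 0.01, seed = 1) {
  if (n_spikes < 0) stopf("n_spikes must be >= 0")
  if (salt_pepper_fraction < 0 || salt_pepper_fraction > 1)
    stopf("salt_pepper_fraction must be in [0, 1]")
  if (spike_width < 1) stopf("spike_width must be >= 1")
  structure(list(n_spikes = as.integer(n_spikes),
                 amplitude_range = sort(amplitude_range),
                 spike_width = as.integer(spike_width),
                 white_noise_sigma = white_noise_sigma,
                 salt_pepper_fraction = salt_pepper_fraction,
                 seed = as.integer(seed)),
            class = "spike_noise_config")
}

#' Plant parasitic spikes into an empty sinogram
#'
#' @param geometry an [array_geometry()].
#' @param n_time number of time samples per channel; must exceed the spike
#'   width.
#' @param config a [spike_noise_config()].
#' @return object of class `sinogram`: list with `samples`
#'   (`n_elements x n_time` matrix) and `geometry`.
#' @export
inject_spikes <- function(geometry, n_time, config) {
  if (n_time <= config$spike_width) stopf("n_time must exceed spike_width")
  if (config$n_spikes > geometry$n_elements * n_time)
    stopf("n_spikes exceeds the sinogram size")
  s <- matrix(0, geometry$n_elements, n_time)
  if (config$n_spikes > 0) {
    with_seed(config$seed, {
      placed <- matrix(NA_real_, 0, 2)
      tries <- 0
      while (nrow(placed) < config$n_spikes && tries < 100000) {
        tries <- tries + 1
        d <- sample.int(geometry$n_elements, 1)
        t0 <- sample.int(n_time - config$spike_width + 1, 1)
        if (nrow(placed) > 0) {
          same <- placed[, 1] == d
          if (any(same) && any(abs(placed[same, 2] - t0) < config$spike_width))
            next  # would merge with an existing spike on this channel
        }
        placed <- rbind(placed, c(d, t0))
      }
      if (nrow(placed) < config$n_spikes)
        stopf("could not place %d non-overlapping spikes", config$n_spikes)
      amp <- runif(config$n_spikes, config$amplitude_range[1],
                   config$amplitude_range[2])
      for (i in seq_len(config$n_spikes))
        s[placed[i, 1], placed[i, 2]:(placed[i, 2] + config$spike_width - 1)] <- amp[i]
    })
  }
  structure(list(samples = s, geometry = geometry), class = "sinogram")
}

#' Delay-and-sum backprojection of a sinogram
#'
#' Simple geometric reconstruction used as plumbing for noise synthesis:
#' each pixel accumulates, over detectors, the sinogram sample whose
#' time-of-flight index matches the pixel-detector distance at the configured
#' speed of sound (time zero at the detector).  Indices falling outside the
#' recorded window contribute zero.  The operator is linear in the sinogram.
#'
#' @param sino a `sinogram` object.
#' @param grid_size output image side length in pixels.
#' @param fov field of view in mm.
#' @return numeric `grid_size x grid_size` matrix.
#' @export
backproject <- function(sino, grid_size, fov = 40) {
  if (!inherits(sino, "sinogram")) stopf("`sino` must be a sinogram object")
  if (fov <= 0) stopf("fov must be > 0")
  geom <- sino$geometry
  if (nrow(sino$samples) != geom$n_elements)
    stopf("sinogram row count does not match geometry$n_elements")
  n_time <- ncol(sino$samples)
  co <- pixel_coords(grid_size, fov)
  X <- matrix(co$x, grid_size, grid_size, byrow = TRUE)
  Y <- matrix(co$y, grid_size, grid_size)
  pos <- detector_positions(geom)
  img <- matrix(0, grid_size, grid_size)
  for (d in seq_len(geom$n_elements)) {
    dist <- sqrt((X - pos[d, 1])^2 + (Y - pos[d, 2])^2)
    idx <- round(dist / geom$speed_of_sound * geom$sampling_rate) + 1
    ok <- idx >= 1 & idx <= n_time
    if (any(ok)) img[ok] <- img[ok] + sino$samples[d, idx[ok]]
  }
  img / geom$n_elements
}

#' Generate a structured ring/arc noise-artifact image
#'
#' Composition `inject_spikes -> backproject -> white noise -> salt & pepper
#' -> normalize`, emulating how parasitic sinogram spikes propagate through
#' reconstruction and appear as rings or arcs in the image.  The
#' backprojected spike image is normalized to `[0, 1]` before the stochastic
#' components are added so that `white_noise_sigma` is expressed on the
#' normalized intensity scale; the final image is normalized again.
#'
#' @param geometry an [array_geometry()].
#' @param config a [spike_noise_config()].
#' @param grid_size image side length in pixels.
#' @param fov field of view in mm.
#' @param n_time sinogram length in samples; defaults to enough samples to
#'   cover the corner-to-corner time of flight.
#' @return numeric matrix in `[0, 1]`.
#' @export
make_ring_noise <- function(geometry, config, grid_size = 128, fov = 40,
                            n_time = NULL) {
  if (is.null(n_time)) {
    dmax <- geometry$radius + fov * sqrt(2) / 2
    n_time <- as.integer(ceiling(dmax / geometry$speed_of_sound *
                                   geometry$sampling_rate)) + 8L
  }
  sino <- inject_spikes(geometry, n_time, config)
  img <- normalize01(backproject(sino, grid_size, fov))
  if (config$white_noise_sigma > 0)
    img <- img + with_seed(derive_seed(config$seed, "white"),
                           matrix(rnorm(length(img), 0, config$white_noise_sigma),
                                  nrow(img)))
  if (config$salt_pepper_fraction > 0) {
    img <- with_seed(derive_seed(config$seed, "saltpepper"), {
      n_sp <- round(config$salt_pepper_fraction * length(img))
      if (n_sp > 0) {
        pos <- sample.int(length(img), n_sp)
        img[pos] <- sample(c(0, 1), n_sp, replace = TRUE)
      }
      img
    })
  }
  normalize01(img)
}
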