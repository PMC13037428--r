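# Paired training data: weighted noise mixing and augmentation.
#
# A training example is a triplet (I_signal, I_noise, w) together with the
# synthetic noisy image I_mixed = w * I_noise + (1 - w) * I_signal, where the
# noise level w in [0, 1] sets the pixel-value weight of the artifact image
# (w = 0.5 means signal and noise carry equal weight).  The network is
# trained to recover the noise component actually present in the mixture.

#' Mix a signal and a noise image at a given noise level
#'
#' Exact element-wise weighted addition `w * noise + (1 - w) * signal`.
#' Both inputs are expected in `[0, 1]`; the convex combination then stays in
#' `[0, 1]` and no re-normalization is applied, which keeps the mixing
#' algebra exactly invertible.
#'
#' @param signal,noise numeric matrices of identical shape.
#' @param w noise level in `[0, 1]`.
#' @return numeric matrix.
#' @examples
#' s <- make_phantom(phantom_config(grid_size = 64, seed = 1))
#' n <- make_ring_noise(array_geometry(), spike_noise_config(seed = 2),
#'                      grid_size = 64)
#' m <- mix_images(s, n, 0.5)   # signal and artifacts at equal weight
#' range(m)
#' @export
mix_images <- function(signal, noise, w) {
  check_image(signal, "signal"); check_image(noise, "noise")
  check_same_shape(signal, noise)
  if (!is.numeric(w) || length(w) != 1 || w < 0 || w > 1)
    stopf("w must be a single number in [0, 1]")
  if (w == 0) return(signal)
  if (w == 1) return(noise)
  w * noise + (1 - w) * signal
}

noise_only_ops <- c("white_noise", "salt_pepper")

#' Augmentation settings
#'
#' @param factor integer dataset multiplier (>= 1); the output of
#'   [augment_image()] includes the original, so `factor = 10` turns 550
#'   source images into 5500.
#' @param ops operations sampled for each derived image.  Allowed for any
#'   image: `crop`, `scale`, `rotate`, `flip`, `brightness_contrast`,
#'   `elastic`; additionally for noise images only: `white_noise`,
#'   `salt_pepper`.
#' @param params list of per-op parameter ranges overriding the defaults.
#' @param seed integer seed; augmentation is deterministic per seed.
#' @export
augmentation_config <- function(factor = 10,
                                ops = c("crop", "scale", "rotate", "flip",
                                        "brightness_contrast", "elastic"),
                                params = list(), seed = 1) {
  if (factor < 1 || factor != round(factor)) stopf("factor must be an integer >= 1")
  known <- c("crop", "scale", "rotate", "flip", "brightness_contrast",
             "elastic", noise_only_ops)
  bad <- setdiff(ops, known)
  if (length(bad)) stopf("unknown augmentation op(s): %s", paste(bad, collapse = ", "))
  defaults <- list(crop_scale = c(0.7, 0.95), zoom = c(0.9, 1.1),
                   angle = c(-20, 20), brightness = c(-0.1, 0.1),
                   contrast = c(0.8, 1.2), elastic_grid = 4,
                   elastic_max_frac = 0.03, white_sigma = c(0.01, 0.05),
                   sp_fraction = c(0.002, 0.02))
  defaults[names(params)] <- params
  structure(list(factor = as.integer(factor), ops = ops, params = defaults,
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Rotate an image about its center
#'
#' Multiples of 90 degrees are exact index permutations; other angles use
#' bilinear interpolation with zero fill, keeping the original image size.
#'
#' @param img numeric matrix.
#' @param angle rotation angle in degrees (counter-clockwise in standard
#'   row/column display orientation).
#' @export
rotate_image <- function(img, angle) {
  check_image(img)
  a <- angle %% 360
  if (a %% 90 == 0) {
    k <- (a %/% 90) %% 4
    out <- img
    if (k >= 1) for (i in seq_len(k)) out <- t(out)[nrow(t(out)):1, , drop = FALSE]
    return(out)
  }
  m <- EBImage::imageData(EBImage::rotate(EBImage::Image(img), angle,
                                          output.dim = dim(img), bg.col = 0))
  matrix(as.numeric(m), nrow(img), ncol(img))
}

resize_image <- function(img, h, w) {
  m <- EBImage::imageData(EBImage::resize(EBImage::Image(img), w = h, h = w))
  matrix(as.numeric(m), h, w)
}

# bilinear lookup of img at fractional (row, col) grids; outside -> edge clamp
bilinear_sample <- function(img, R, C) {
  H <- nrow(img); W <- ncol(img)
  R <- pmin(pmax(R, 1), H); C <- pmin(pmax(C, 1), W)
  r0 <- floor(R); c0 <- floor(C)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- R - r0; fc <- C - c0
  v00 <- img[cbind(as.vector(r0), as.vector(c0))]
  v01 <- img[cbind(as.vector(r0), as.vector(c1))]
  v10 <- img[cbind(as.vector(r1), as.vector(c0))]
  v11 <- img[cbind(as.vector(r1), as.vector(c1))]
  out <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
  matrix(out, H, W)
}

elastic_deform <- function(img, grid_n, max_disp) {
  H <- nrow(img); W <- ncol(img)
  dx <- matrix(runif(grid_n^2, -max_disp, max_disp), grid_n)
  dy <- matrix(runif(grid_n^2, -max_disp, max_disp), grid_n)
  DX <- resize_image(dx, H, W); DY <- resize_image(dy, H, W)
  R <- matrix(seq_len(H), H, W) + DY
  C <- matrix(seq_len(W), H, W, byrow = TRUE) + DX
  bilinear_sample(img, R, C)
}

apply_aug_op <- function(img, op, p) {
  n <- nrow(img)
  switch(op,
    crop = {
      u <- runif(1, p$crop_scale[1], p$crop_scale[2])
      s <- max(8, round(n * u))
      r0 <- sample.int(n - s + 1, 1); c0 <- sample.int(n - s + 1, 1)
      resize_image(img[r0:(r0 + s - 1), c0:(c0 + s - 1)], n, n)
    },
    scale = {
      z <- runif(1, p$zoom[1], p$zoom[2])
      s <- max(8, round(n * z))
      m <- resize_image(img, s, s)
      if (s >= n) {
        o <- (s - n) %/% 2
        m[(o + 1):(o + n), (o + 1):(o + n)]
      } else {
        out <- matrix(0, n, n); o <- (n - s) %/% 2
        out[(o + 1):(o + s), (o + 1):(o + s)] <- m
        out
      }
    },
    rotate = rotate_image(img, runif(1, p$angle[1], p$angle[2])),
    flip = if (runif(1) < 0.5) img[, ncol(img):1] else img[nrow(img):1, ],
    brightness_contrast = {
      a <- runif(1, p$contrast[1], p$contrast[2])
      b <- runif(1, p$brightness[1], p$brightness[2])
      clip01(a * img + b)
    },
    elastic = elastic_deform(img, p$elastic_grid, p$elastic_max_frac * n),
    white_noise = {
      s <- runif(1, p$white_sigma[1], p$white_sigma[2])
      clip01(img + matrix(rnorm(length(img), 0, s), nrow(img)))
    },
    salt_pepper = {
      f <- runif(1, p$sp_fraction[1], p$sp_fraction[2])
      k <- max(1, round(f * length(img)))
      pos <- sample.int(length(img), k)
      img[pos] <- sample(c(0, 1), k, replace = TRUE)
      img
    },
    stopf("unknown op '%s'", op))
}

#' Augment an image into a deterministic family of variants
#'
#' Returns `factor` images: the original followed by `factor - 1` derived
#' images, each obtained by one operation sampled from the allowed set with
#' random parameters.  The ops applied to each variant are recorded in the
#' `aug_ops` attribute.  Noise-specific ops (`white_noise`, `salt_pepper`)
#' are rejected unless `is_noise = TRUE`.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param config an [augmentation_config()].
#' @param is_noise whether `img` is a noise-artifact image.
#' @return list of `config$factor` matrices.
#' @export
augment_image <- function(img, config, is_noise = FALSE) {
  check_image(img)
  if (!inherits(config, "augmentation_config"))
    stopf("config must be an augmentation_config")
  allowed <- config$ops
  if (!is_noise) {
    bad <- intersect(allowed, noise_only_ops)
    if (length(bad))
      stopf("op(s) %s only allowed for noise images", paste(bad, collapse = ", "))
  } else {
    allowed <- unique(c(allowed, noise_only_ops))
  }
  orig <- img
  attr(orig, "aug_ops") <- "identity"
  out <- vector("list", config$factor)
  out[[1]] <- orig
  if (config$factor > 1) {
    with_seed(config$seed, {
      for (i in 2:config$factor) {
        op <- sample(allowed, 1)
        im <- apply_aug_op(img, op, config$params)
        attr(im, "aug_ops") <- op
        out[[i]] <- im
      }
    })
  }
  out
}

#' Train/validation/test split sizes
#'
#' Counts of source images per partition, for the signal and noise
#' categories separately.  The three index sets are pairwise disjoint within
#' each category so no source image leaks across partitions.
#'
#' @param train,val,test signal-image counts.
#' @param noise_train,noise_val,noise_test noise-image counts (default: same
#'   as the signal counts).
#' @export
split_spec <- function(train, val, test, noise_train = train,
                       noise_val = val, noise_test = test) {
  v <- c(train, val, test, noise_train, noise_val, noise_test)
  if (any(v < 0) || any(v != round(v))) stopf("split counts must be non-negative integers")
  if (train < 1 || val < 1 || test < 1) stopf("empty partitions are not allowed")
  structure(list(train = train, val = val, test = test,
                 noise_train = noise_train, noise_val = noise_val,
                 noise_test = noise_test),
            class = "split_spec")
}

new_triplet <- function(signal, noise, w, signal_src = NA, noise_src = NA,
                        aug_ops = "identity") {
  structure(list(signal = signal, noise = noise, w = w,
                 mixed = mix_images(signal, noise, w),
                 meta = list(signal_src = signal_src, noise_src = noise_src,
                             aug_ops = aug_ops)),
            class = "oa_triplet")
}

#' Build paired train/val/test collections of noisy triplets
#'
#' Source images are partitioned disjointly per category, augmentation is
#' applied to the training partition only, each training triplet draws its
#' noise level `w` uniformly from `w_range`, and validation/test triplets use
#' the fixed grid `w in {0.3, 0.5, 0.7}` representative of the noise levels
#' encountered in practice.
#'
#' @param signals,noises lists of numeric matrices in `[0, 1]`.
#' @param split a [split_spec()].
#' @param aug an [augmentation_config()]; `factor = 1` disables augmentation.
#' @param w_range training noise-level interval, default `[0.1, 0.9]`.
#' @param w_grid validation/test noise levels.
#' @param seed master seed for partitioning, pairing and `w` sampling.
#' @return an object of class `oa_dataset`: list with `train`, `val`, `test`
#'   triplet lists and a provenance `manifest` data frame.
#' @export
build_dataset <- function(signals, noises, split, aug = augmentation_config(1),
                          w_range = c(0.1, 0.9), w_grid = c(0.3, 0.5, 0.7),
                          seed = 1) {
  signals <- as_image_list(signals); noises <- as_image_list(noises)
  if (!inherits(split, "split_spec")) stopf("split must be a split_spec")
  need_s <- split$train + split$val + split$test
  need_n <- split$noise_train + split$noise_val + split$noise_test
  if (need_s > length(signals))
    stopf("split requests %d signal images but only %d provided", need_s, length(signals))
  if (need_n > length(noises))
    stopf("split requests %d noise images but only %d provided", need_n, length(noises))
  if (any(w_range < 0) || any(w_range > 1) || diff(range(w_range)) < 0)
    stopf("w_range must be within [0, 1]")

  perm_s <- with_seed(derive_seed(seed, "split-signal"), sample.int(length(signals)))
  perm_n <- with_seed(derive_seed(seed, "split-noise"), sample.int(length(noises)))
  idx_s <- list(train = perm_s[seq_len(split$train)],
                val = perm_s[split$train + seq_len(split$val)],
                test = perm_s[split$train + split$val + seq_len(split$test)])
  idx_n <- list(train = perm_n[seq_len(split$noise_train)],
                val = perm_n[split$noise_train + seq_len(split$noise_val)],
                test = perm_n[split$noise_train + split$noise_val +
                                seq_len(split$noise_test)])

  # training: augmented, w ~ U(w_range), random signal-noise pairing
  train <- list()
  noise_pool <- list(); noise_pool_src <- integer(0)
  for (j in idx_n$train) {
    aug_j <- aug; aug_j$seed <- derive_seed(aug$seed, paste0("noise:", j))
    av <- augment_image(noises[[j]], aug_j, is_noise = TRUE)
    noise_pool <- c(noise_pool, av)
    noise_pool_src <- c(noise_pool_src, rep(j, length(av)))
  }
  k <- 0
  for (i in idx_s$train) {
    aug_i <- aug; aug_i$seed <- derive_seed(aug$seed, paste0("signal:", i))
    av <- augment_image(signals[[i]], aug_i, is_noise = FALSE)
    for (s_img in av) {
      k <- k + 1
      pick <- with_seed(derive_seed(seed, paste0("pair:", k)),
                        sample.int(length(noise_pool), 1))
      w <- with_seed(derive_seed(seed, paste0("w:", k)),
                     runif(1, w_range[1], w_range[2]))
      train[[k]] <- new_triplet(s_img, noise_pool[[pick]], w,
                                signal_src = i, noise_src = noise_pool_src[pick],
                                aug_ops = attr(s_img, "aug_ops"))
    }
  }

  fixed_part <- function(part) {
    out <- list(); k <- 0
    ns <- idx_n[[part]]
    for (ii in seq_along(idx_s[[part]])) {
      i <- idx_s[[part]][ii]
      for (w in w_grid) {
        k <- k + 1
        j <- ns[(k - 1) %% length(ns) + 1]
        out[[k]] <- new_triplet(signals[[i]], noises[[j]], w,
                                signal_src = i, noise_src = j)
      }
    }
    out
  }
  val <- fixed_part("val")
  test <- fixed_part("test")

  mk_rows <- function(lst, part)
    data.frame(partition = part,
               signal_src = vapply(lst, function(t) t$meta$signal_src, numeric(1)),
               noise_src = vapply(lst, function(t) t$meta$noise_src, numeric(1)),
               w = vapply(lst, function(t) t$w, numeric(1)),
               aug_ops = vapply(lst, function(t) t$meta$aug_ops, character(1)),
               stringsAsFactors = FALSE)
  manifest <- rbind(mk_rows(train, "train"), mk_rows(val, "val"),
                    mk_rows(test, "test"))
  structure(list(train = train, val = val, test = test, manifest = manifest,
                 w_range = w_range, w_grid = w_grid, seed = seed),
            class = "oa_dataset")
}

#' @export
print.oa_dataset <- function(x, ...) {
  cat("Paired optoacoustic denoising dataset\n")
  cat(sprintf("  train: %d triplets (w in [%.2f, %.2f])\n", length(x$train),
              x$w_range[1], x$w_range[2]))
  cat(sprintf("  val:   %d triplets (w grid %s)\n", length(x$val),
              paste(x$w_grid, collapse = ", ")))
  cat(sprintf("  test:  %d triplets\n", length(x$test)))
  invisible(x)
}
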