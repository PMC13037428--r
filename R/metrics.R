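# Quantitative image-quality evaluation: visual information fidelity (VIF),
# PSNR, contrast-to-noise ratio over explicit ROIs, and the pairwise
# background-variability summary used to characterize how repeatable
# background-only acquisitions are.

#' VIF settings
#'
#' @param n_scales number of dyadic scales (successive 2x smoothed
#'   downsampling).
#' @param block local window side length; statistics are computed over
#'   non-overlapping `block x block` windows (partial border windows are
#'   dropped).
#' @param sigma_n_sq the fixed visual-noise variance constant of the VIF
#'   model (dimensionless, on the squared intensity scale).
#' @param variance_floor floor used when dividing by the reference variance.
#' @export
vif_config <- function(n_scales = 4, block = 8, sigma_n_sq = 2,
                       variance_floor = 1e-10) {
  if (n_scales < 1) stopf("n_scales must be >= 1")
  if (sigma_n_sq <= 0) stopf("sigma_n_sq must be > 0")
  if (variance_floor <= 0) stopf("variance_floor must be > 0")
  structure(list(n_scales = as.integer(n_scales), block = as.integer(block),
                 sigma_n_sq = sigma_n_sq, variance_floor = variance_floor),
            class = "vif_config")
}

block_means <- function(m, b) {
  h2 <- nrow(m) %/% b; w2 <- ncol(m) %/% b
  m <- m[seq_len(h2 * b), seq_len(w2 * b), drop = FALSE]
  s <- rowsum(m, rep(seq_len(h2), each = b))
  t(rowsum(t(s), rep(seq_len(w2), each = b))) / b^2
}

# 5-tap binomial smoothing followed by 2x decimation
smooth_decimate <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  s <- cpp_sepconv_valid(m, k)
  s[seq(1, nrow(s), 2), seq(1, ncol(s), 2), drop = FALSE]
}

#' Visual information fidelity between a reference and a processed image
#'
#' Decomposes both images into `n_scales` scales and, per non-overlapping
#' block, computes the reference variance, the processed variance and their
#' covariance; the gain factor `g = cov / var_ref` and the distortion noise
#' variance `sv2 = var_proc - g * cov` (clamped at zero) then enter
#'
#' `VIF = sum log10(1 + g^2 var_ref / (sv2 + sigma_n^2)) /
#'        sum log10(1 + var_ref / sigma_n^2)`
#'
#' with both sums running over blocks and scales.  `vif(x, x)` equals 1
#' exactly; for a degraded version of the reference the score falls towards
#' 0, so higher means better information preservation.
#'
#' @param gt reference (ground-truth) image.
#' @param p processed image of the same shape.
#' @param cfg a [vif_config()].
#' @return scalar score.
#' @examples
#' s <- make_phantom(phantom_config(grid_size = 64, seed = 1))
#' n <- make_ring_noise(array_geometry(), spike_noise_config(seed = 2),
#'                      grid_size = 64)
#' vif(s, s)                         # identity: exactly 1
#' vif(s, mix_images(s, n, 0.5))     # fidelity drops with corruption
#' @export
vif <- function(gt, p, cfg = vif_config()) {
  check_image(gt, "gt"); check_image(p, "p"); check_same_shape(gt, p)
  if (min(dim(gt)) < cfg$block)
    stopf("image too small for block size %d", cfg$block)
  num <- 0; den <- 0
  x <- gt; y <- p
  for (s in seq_len(cfg$n_scales)) {
    if (s > 1) {
      if (min(dim(x)) < max(5, 2 * cfg$block)) break  # no blocks left coarser
      x <- smooth_decimate(x); y <- smooth_decimate(y)
      if (min(dim(x)) < cfg$block) break
    }
    ex <- block_means(x, cfg$block); ey <- block_means(y, cfg$block)
    var_gt <- block_means(x * x, cfg$block) - ex^2
    var_p <- block_means(y * y, cfg$block) - ey^2
    cov <- block_means(x * y, cfg$block) - ex * ey
    g <- cov / pmax(var_gt, cfg$variance_floor)
    sv2 <- pmax(var_p - g * cov, 0)
    num <- num + sum(log10(1 + g^2 * var_gt / (sv2 + cfg$sigma_n_sq)))
    den <- den + sum(log10(1 + var_gt / cfg$sigma_n_sq))
  }
  if (den == 0)
    stopf("reference image is constant at every scale; VIF undefined")
  num / den
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(data_range^2 / MSE)`; identical images give `Inf`.
#'
#' @param gt,p images of identical shape.
#' @param data_range peak-to-peak intensity range (1 for normalized images).
#' @return value in dB.
#' @export
psnr <- function(gt, p, data_range = 1) {
  check_same_shape(gt, p)
  mse <- mean((gt - p)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Region-of-interest specification for CNR
#'
#' Two non-overlapping axis-aligned rectangles given 1-based as
#' `c(row0, col0, height, width)`: the object ROI and a background region
#' chosen outside the imaged body.
#'
#' @param roi,background integer vectors `c(row0, col0, height, width)`.
#' @export
roi_spec <- function(roi, background) {
  chk <- function(r, nm) {
    if (length(r) != 4 || any(r[3:4] < 1) || any(r[1:2] < 1))
      stopf("%s must be c(row0, col0, height, width) with positive sizes", nm)
    as.integer(r)
  }
  roi <- chk(roi, "roi"); background <- chk(background, "background")
  r1 <- c(roi[1], roi[1] + roi[3] - 1, roi[2], roi[2] + roi[4] - 1)
  r2 <- c(background[1], background[1] + background[3] - 1,
          background[2], background[2] + background[4] - 1)
  if (r1[1] <= r2[2] && r2[1] <= r1[2] && r1[3] <= r2[4] && r2[3] <= r1[4])
    stopf("roi and background rectangles overlap")
  structure(list(roi = roi, background = background), class = "roi_spec")
}

extract_rect <- function(img, r) {
  if (r[1] + r[3] - 1 > nrow(img) || r[2] + r[4] - 1 > ncol(img))
    stopf("rectangle falls outside the image")
  img[r[1]:(r[1] + r[3] - 1), r[2]:(r[2] + r[4] - 1)]
}

#' Contrast-to-noise ratio
#'
#' `(mean(ROI) - mean(background)) / sd(background)` with the unbiased
#' standard deviation — the most common CNR convention.  Invariant to
#' adding a constant to the whole image.
#'
#' @param img numeric matrix.
#' @param roi a [roi_spec()].
#' @export
cnr <- function(img, roi) {
  if (!inherits(roi, "roi_spec")) stopf("roi must be a roi_spec")
  a <- extract_rect(img, roi$roi)
  b <- extract_rect(img, roi$background)
  sb <- stats::sd(as.vector(b))
  if (sb == 0) stopf("degenerate background region (zero variance)")
  (mean(a) - mean(b)) / sb
}

#' Automatic ROI placement from a known clean signal image
#'
#' Centers the object ROI on the brightest pixel of the reference signal
#' (clamped inside the image) and places the background square in the
#' top-left corner, which lies outside the elliptical body for the phantoms
#' generated here.
#'
#' @param signal clean reference image.
#' @param roi_size side length of the object ROI.
#' @param bg_size side length of the background square.
#' @export
auto_roi <- function(signal, roi_size = 7, bg_size = 10) {
  check_image(signal)
  pk <- which(signal == max(signal), arr.ind = TRUE)[1, ]
  h <- nrow(signal); w <- ncol(signal)
  r0 <- min(max(pk[1] - roi_size %/% 2, bg_size + 2), h - roi_size + 1)
  c0 <- min(max(pk[2] - roi_size %/% 2, bg_size + 2), w - roi_size + 1)
  roi_spec(c(r0, c0, roi_size, roi_size), c(1, 1, bg_size, bg_size))
}

#' Pairwise variability of a frame stack
#'
#' Quantifies how repeatable repeated acquisitions are by computing SSIM and
#' PSNR over unordered frame pairs — all pairs when their number does not
#' exceed `max_pairs`, otherwise a seeded random subsample.
#'
#' @param frames list of matrices or 3-d array, at least 2 frames.
#' @param max_pairs cap on the number of evaluated pairs.
#' @param seed subsampling seed.
#' @param data_range intensity range; default: global range of the stack
#'   (1 if the stack is constant).
#' @return list with per-metric `mean`, `sd`, `q05`, `q95` and `n_pairs`.
#' @export
pairwise_variability <- function(frames, max_pairs = 500, seed = 1,
                                 data_range = NULL) {
  fr <- as_image_list(frames)
  if (length(fr) < 2) stopf("need at least 2 frames")
  if (is.null(data_range)) {
    r <- range(unlist(lapply(fr, range)))
    data_range <- if (r[2] - r[1] > 0) r[2] - r[1] else 1
  }
  pairs <- utils::combn(length(fr), 2)
  if (ncol(pairs) > max_pairs) {
    keep <- with_seed(seed, sample.int(ncol(pairs), max_pairs))
    pairs <- pairs[, keep, drop = FALSE]
  }
  sv <- pv <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- fr[[pairs[1, i]]]; b <- fr[[pairs[2, i]]]
    sv[i] <- ssim(a, b, data_range = data_range)
    pv[i] <- psnr(a, b, data_range = data_range)
  }
  summ <- function(v) {
    fin <- v[is.finite(v)]
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
      q05 = unname(quantile(fin, 0.05)), q95 = unname(quantile(fin, 0.95)))
  }
  list(ssim = summ(sv), psnr = summ(pv), n_pairs = ncol(pairs),
       ssim_values = sv, psnr_values = pv)
}

#' Per-image quality report
#'
#' Computes VIF, PSNR, SSIM and (when ROIs are supplied) CNR for each
#' processed image against its reference, echoing the ROI rectangles for
#' provenance.
#'
#' @param gts,ps lists of reference and processed images.
#' @param rois optional list of [roi_spec()] (recycled if length 1).
#' @param vif_cfg a [vif_config()].
#' @param data_range intensity range for PSNR/SSIM.
#' @return data frame of class `quality_report`.
#' @export
quality_report <- function(gts, ps, rois = NULL, vif_cfg = vif_config(),
                           data_range = 1) {
  gts <- as_image_list(gts); ps <- as_image_list(ps)
  if (length(gts) != length(ps)) stopf("reference/processed counts differ")
  n <- length(gts)
  if (!is.null(rois) && inherits(rois, "roi_spec")) rois <- list(rois)
  if (!is.null(rois) && length(rois) == 1) rois <- rep(rois, n)
  out <- data.frame(image = seq_len(n), vif = NA_real_, psnr = NA_real_,
                    ssim = NA_real_, cnr = NA_real_, roi = NA_character_)
  for (i in seq_len(n)) {
    out$vif[i] <- vif(gts[[i]], ps[[i]], vif_cfg)
    out$psnr[i] <- psnr(gts[[i]], ps[[i]], data_range)
    out$ssim[i] <- ssim(gts[[i]], ps[[i]], data_range)
    if (!is.null(rois)) {
      out$cnr[i] <- cnr(ps[[i]], rois[[i]])
      out$roi[i] <- paste(c(rois[[i]]$roi, rois[[i]]$background), collapse = ",")
    }
  }
  class(out) <- c("quality_report", "data.frame")
  out
}

#' Write a quality report to JSON or CSV (by extension)
#' @param report a `quality_report`.
#' @param path output path ending in `.json` or `.csv`.
#' @export
write_quality_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  else write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
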