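# Structural similarity (SSIM) and its multiscale variant, with analytic
# gradients with respect to the second (processed/predicted) image so both
# can serve as differentiable loss-evaluation modules.  Local statistics use
# an 11x11 Gaussian window (sigma 1.5) over the valid region, constants
# K1 = 0.01, K2 = 0.03 on the configured data range.

gauss_kernel <- function(window = 11, sigma = 1.5) {
  u <- seq(-(window - 1) / 2, (window - 1) / 2)
  k <- exp(-u^2 / (2 * sigma^2))
  k / sum(k)
}

ssim_stats <- function(x, y, k) {
  V <- function(m) cpp_sepconv_valid(m, k)
  mux <- V(x); muy <- V(y)
  list(mux = mux, muy = muy,
       sx2 = V(x * x) - mux^2, sy2 = V(y * y) - muy^2,
       sxy = V(x * y) - mux * muy)
}

ssim_terms <- function(st, C1, C2) {
  list(A1 = 2 * st$mux * st$muy + C1, A2 = 2 * st$sxy + C2,
       B1 = st$mux^2 + st$muy^2 + C1, B2 = st$sx2 + st$sy2 + C2)
}

#' Structural similarity index between two images
#'
#' @param x reference image (numeric matrix).
#' @param y processed image, same shape.
#' @param data_range intensity range of the data (1 for normalized images).
#' @param window Gaussian window size (odd).
#' @param sigma Gaussian window standard deviation.
#' @return mean SSIM over the valid region (scalar in `[-1, 1]`).
#' @export
ssim <- function(x, y, data_range = 1, window = 11, sigma = 1.5) {
  check_image(x, "x"); check_image(y, "y"); check_same_shape(x, y)
  k <- gauss_kernel(window, sigma)
  st <- ssim_stats(x, y, k)
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  tm <- ssim_terms(st, C1, C2)
  mean(tm$A1 * tm$A2 / (tm$B1 * tm$B2))
}

# mean SSIM and its gradient wrt y; cs_only drops the luminance term
# (the contrast-structure component used by intermediate MS-SSIM scales)
ssim_with_grad <- function(x, y, data_range = 1, window = 11, sigma = 1.5,
                           cs_only = FALSE) {
  k <- gauss_kernel(window, sigma)
  st <- ssim_stats(x, y, k)
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  tm <- ssim_terms(st, C1, C2)
  M <- length(tm$A1)
  if (cs_only) {
    S <- tm$A2 / tm$B2
    G1 <- matrix(0, nrow(S), ncol(S))
    G2 <- -tm$A2 / tm$B2^2
    G3 <- 2 / tm$B2
  } else {
    S <- tm$A1 * tm$A2 / (tm$B1 * tm$B2)
    G1 <- (tm$A2 / tm$B2) * 2 * (st$mux * tm$B1 - st$muy * tm$A1) / tm$B1^2
    G2 <- -tm$A1 * tm$A2 / (tm$B1 * tm$B2^2)
    G3 <- (tm$A1 / tm$B1) * (2 / tm$B2)
  }
  H <- nrow(x); W <- ncol(x)
  Vt <- function(m) cpp_sepconv_valid_t(m, k, H, W)
  grad <- (Vt(G1 - 2 * st$muy * G2 - st$mux * G3) +
             2 * y * Vt(G2) + x * Vt(G3)) / M
  list(value = mean(S), grad = grad)
}

down2 <- function(m) {
  h <- (nrow(m) %/% 2) * 2; w <- (ncol(m) %/% 2) * 2
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  (m[seq(1, h, 2), seq(1, w, 2), drop = FALSE] +
     m[seq(2, h, 2), seq(1, w, 2), drop = FALSE] +
     m[seq(1, h, 2), seq(2, w, 2), drop = FALSE] +
     m[seq(2, h, 2), seq(2, w, 2), drop = FALSE]) / 4
}

up2_grad <- function(g, H, W) {
  out <- matrix(0, H, W)
  gg <- kronecker(g, matrix(1, 2, 2)) / 4
  out[seq_len(nrow(gg)), seq_len(ncol(gg))] <- gg
  out
}

ms_weights_std <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)

#' Multiscale structural similarity (MS-SSIM)
#'
#' Contrast-structure terms at every scale (2x average-pool downsampling
#' between scales), full SSIM at the coarsest scale, combined as the
#' weighted geometric mean with the standard five-scale weights
#' (renormalized when fewer scales are requested).
#'
#' @inheritParams ssim
#' @param scales number of scales (default 5); the image must still contain
#'   the analysis window at the coarsest scale.
#' @export
ms_ssim <- function(x, y, data_range = 1, window = 11, sigma = 1.5,
                    scales = 5) {
  ms_ssim_with_grad(x, y, data_range, window, sigma, scales,
                    want_grad = FALSE)$value
}

ms_ssim_with_grad <- function(x, y, data_range = 1, window = 11, sigma = 1.5,
                              scales = 5, want_grad = TRUE) {
  check_image(x, "x"); check_image(y, "y"); check_same_shape(x, y)
  if (min(dim(x)) < window * 2^(scales - 1))
    stopf("image (%dx%d) smaller than the smallest MS-SSIM scale (needs >= %d px)",
          nrow(x), ncol(x), window * 2^(scales - 1))
  w <- ms_weights_std[seq_len(scales)]
  w <- w / sum(w)
  xs <- list(x); ys <- list(y)
  for (s in seq_len(scales - 1)) {
    xs[[s + 1]] <- down2(xs[[s]]); ys[[s + 1]] <- down2(ys[[s]])
  }
  vals <- numeric(scales); grads <- vector("list", scales)
  for (s in seq_len(scales)) {
    r <- ssim_with_grad(xs[[s]], ys[[s]], data_range, window, sigma,
                        cs_only = s < scales)
    vals[s] <- r$value; grads[[s]] <- r$grad
  }
  clamped <- pmax(vals, 1e-6)
  value <- prod(clamped^w)
  if (!want_grad) return(list(value = value))
  grad <- matrix(0, nrow(x), ncol(x))
  for (s in seq_len(scales)) {
    if (vals[s] < 1e-6) next                     # clamped: no gradient flow
    g <- value * w[s] / clamped[s] * grads[[s]]
    if (s > 1) for (q in seq(s - 1, 1)) g <- up2_grad(g, nrow(ys[[q]]), ncol(ys[[q]]))
    grad <- grad + g
  }
  list(value = value, grad = grad)
}
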