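# Acquisition-side preprocessing: background subtraction, motion rejection
# by correlation clustering, and frame averaging.

#' Subtract a background acquisition from a measurement
#'
#' Plain element-wise difference with no clipping; signed values are allowed
#' downstream.  Works on images, sinogram sample matrices, or whole
#' `sinogram` objects of identical shape.
#'
#' @param measurement,background numeric matrices (or `sinogram` objects) of
#'   identical shape.
#' @export
subtract_background <- function(measurement, background) {
  if (inherits(measurement, "sinogram")) {
    bg <- if (inherits(background, "sinogram")) background$samples else background
    check_same_shape(measurement$samples, bg)
    measurement$samples <- measurement$samples - bg
    return(measurement)
  }
  check_same_shape(measurement, background)
  measurement - background
}

#' Average a subset of frames
#'
#' @param stack list of numeric matrices of identical shape (or 3-d array).
#' @param indices frame indices to average; must be nonempty and in range.
#' @return the arithmetic mean frame.
#' @export
average_frames <- function(stack, indices = NULL) {
  frames <- as_image_list(stack)
  if (is.null(indices)) indices <- seq_along(frames)
  if (length(indices) == 0) stopf("empty index set")
  if (any(indices < 1 | indices > length(frames))) stopf("frame index out of range")
  out <- frames[[indices[1]]]
  if (length(indices) > 1)
    for (i in indices[-1]) out <- out + frames[[i]]
  out / length(indices)
}

# deterministic farthest-point center seeding; ties broken by lowest index
farthest_point_centers <- function(X, k) {
  n <- nrow(X)
  gm <- colMeans(X)
  d0 <- rowSums(sweep(X, 2, gm)^2)
  centers <- which.max(d0)            # which.max takes the lowest index on ties
  while (length(centers) < k) {
    dmin <- rep(Inf, n)
    for (c in centers) {
      dc <- rowSums(sweep(X, 2, X[c, ])^2)
      dmin <- pmin(dmin, dc)
    }
    dmin[centers] <- -Inf
    centers <- c(centers, which.max(dmin))
  }
  X[centers, , drop = FALSE]
}

#' Reject motion-corrupted frames by clustering the correlation matrix
#'
#' Computes the Pearson correlation matrix over flattened frames, clusters
#' its rows with k-means (k = 2 by default, deterministic farthest-point
#' center seeding), keeps the cluster whose members have the highest mean
#' intra-cluster pairwise correlation — robust even when motion frames are
#' the majority — and averages the kept frames.  Frames with zero variance
#' cannot enter the correlation and are rejected with a warning.
#'
#' @param stack list of numeric matrices of identical shape (or 3-d array);
#'   frames may be sinogram sample matrices or images.
#' @param k number of clusters (default 2); requires at least `k` frames.
#' @return an object of class `motion_report`: list with
#'   `correlation_matrix`, `kept`, `rejected`, `averaged`.
#' @export
motion_reject <- function(stack, k = 2) {
  frames <- as_image_list(stack)
  n <- length(frames)
  if (k < 2) stopf("k must be >= 2")
  if (n < k) stopf("need at least k = %d frames, got %d", k, n)
  flat <- vapply(frames, as.vector, numeric(length(frames[[1]])))
  sds <- apply(flat, 2, stats::sd)
  degenerate <- which(sds == 0)
  usable <- setdiff(seq_len(n), degenerate)
  if (length(degenerate)) {
    warning(sprintf("%d constant frame(s) excluded from correlation and rejected",
                    length(degenerate)), call. = FALSE)
    if (length(usable) < 2) stopf("fewer than 2 usable frames")
  }
  R <- matrix(NA_real_, n, n)
  R[usable, usable] <- stats::cor(flat[, usable, drop = FALSE])
  diag(R) <- 1

  Ru <- R[usable, usable, drop = FALSE]
  # all usable frames effectively identical: nothing to reject
  if (max(stats::dist(Ru)) < 1e-12) {
    kept <- usable
  } else {
    centers <- farthest_point_centers(Ru, min(k, length(usable)))
    cl <- stats::kmeans(Ru, centers = centers, iter.max = 100,
                        algorithm = "Lloyd")$cluster
    intra <- vapply(seq_len(max(cl)), function(g) {
      m <- Ru[cl == g, cl == g, drop = FALSE]
      if (nrow(m) < 2) return(-Inf)
      mean(m[upper.tri(m)])
    }, numeric(1))
    best <- which.max(intra)
    if (!is.finite(intra[best])) best <- which.max(tabulate(cl))
    # when both clusters are comparably tight the intra-correlation estimate
    # of a small cluster is dominated by noise; break near-ties toward the
    # larger cluster
    sizes <- tabulate(cl, nbins = max(cl))
    near <- which(is.finite(intra) & intra >= intra[best] - 0.01)
    if (length(near) > 1) best <- near[which.max(sizes[near])]
    kept <- usable[cl == best]
  }
  rejected <- setdiff(seq_len(n), kept)
  structure(list(correlation_matrix = R, kept = sort(kept),
                 rejected = sort(rejected),
                 averaged = average_frames(frames, sort(kept))),
            class = "motion_report")
}

#' @export
print.motion_report <- function(x, ...) {
  cat(sprintf("Motion rejection: kept %d / %d frames\n", length(x$kept),
              length(x$kept) + length(x$rejected)))
  if (length(x$rejected))
    cat("  rejected:", paste(x$rejected, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a motion report to JSON
#'
#' @param report a `motion_report`.
#' @param path output file.
#' @export
write_motion_report <- function(report, path) {
  ks <- report$kept; rj <- report$rejected
  off <- report$correlation_matrix
  diag(off) <- NA
  jsonlite::write_json(list(
    kept = ks, rejected = rj,
    mean_correlation_kept = mean(off[ks, ks], na.rm = TRUE),
    mean_correlation_rejected = if (length(rj))
      mean(off[rj, , drop = FALSE], na.rm = TRUE) else NULL
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
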