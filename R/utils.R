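# internal helpers shared across modules

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Every stochastic component of the pipeline draws its seed from one master
#' seed through this function, so that a full run is reproducible from
#' `(config, master seed)` without hidden global RNG state.  The mapping
#' hashes the label characters into a 31-bit integer.
#'
#' @param master integer master seed.
#' @param label character tag naming the consumer (e.g. `"augment:12"`).
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(as.numeric(master)) %% 65011 * 33029 + h) %% 2147483629)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stopf("`%s` must be a numeric matrix", arg)
  if (!all(is.finite(img))) stopf("`%s` contains non-finite values", arg)
  invisible(img)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stopf("%s must have identical shapes (got %s vs %s)", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(NULL)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)  # x first: pmax/pmin keep dim from it

#' Normalize an image to the unit interval
#'
#' Linear min-max rescaling.  A constant image maps to all zeros, which keeps
#' degenerate noise configurations well defined instead of dividing by zero.
#'
#' @param img numeric matrix.
#' @return matrix with values in `[0, 1]`.
#' @export
normalize01 <- function(img) {
  check_image(img)
  r <- range(img)
  if (r[2] - r[1] <= 0) return(array(0, dim(img)))
  (img - r[1]) / (r[2] - r[1])
}

# --- batch layout conversion for the C++ engine -------------------------------
# the engine stores a batch as one vector: image-major, row-major pixels
imgs_to_vec <- function(imgs) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  if (is.array(imgs) && length(dim(imgs)) == 3)
    imgs <- lapply(seq_len(dim(imgs)[3]), function(i) imgs[, , i])
  unlist(lapply(imgs, function(m) as.vector(t(m))), use.names = FALSE)
}

vec_to_imgs <- function(v, H, W, N) {
  lapply(seq_len(N), function(n) {
    t(matrix(v[((n - 1) * H * W + 1):(n * H * W)], nrow = W))
  })
}

as_image_list <- function(x) {
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 3)
    return(lapply(seq_len(dim(x)[3]), function(i) x[, , i]))
  if (is.list(x)) return(x)
  stopf("expected a matrix, 3-d array or list of matrices")
}
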