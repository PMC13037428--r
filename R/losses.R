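# Interchangeable loss-evaluation modules.
#
# Training steers on the difference between the inferred and the actual
# noise-artifact image.  The comparison can be a mathematical loss (MSE,
# MAE, 1 - SSIM, 1 - MS-SSIM) or a perceptual loss: the L2 distance between
# intermediate feature maps of a convolutional extractor, averaged over the
# tapped stages.  Pretrained extractor weights are not bundled; the default
# extractor is a fixed-architecture pyramid with seeded random weights,
# which preserves the perceptual-loss mechanism without any download, and
# VGG-style topologies accept a user-supplied weights file.

extractor_plans <- list(
  random_pyramid = list(nconv = c(1L, 1L, 1L), chan = c(8L, 16L, 32L),
                        taps = 0:2, act = 3L),
  vgg19_style = list(nconv = c(2L, 2L, 4L, 4L), chan = c(64L, 128L, 256L, 512L),
                     taps = 1:3, act = 2L),
  vgg16_style = list(nconv = c(2L, 2L, 3L, 3L), chan = c(64L, 128L, 256L, 512L),
                     taps = 1:3, act = 2L),
  resnet50_style = list(nconv = c(1L, 3L, 4L, 6L), chan = c(64L, 128L, 256L, 512L),
                        taps = 1:3, act = 2L)
)

#' Specify a loss-evaluation module
#'
#' @param kind one of `"perceptual"`, `"mse"`, `"mae"`, `"ssim"`,
#'   `"ms_ssim"` (the SSIM kinds are used as `1 - index`).
#' @param extractor perceptual only: `"random_pyramid"` (default; seeded
#'   random weights, no download needed), `"vgg19_style"`, `"vgg16_style"`
#'   or `"resnet50_style"` (stage topologies mirroring the named networks;
#'   the ResNet50 variant matches the stage widths without residual
#'   shortcuts).
#' @param layer_taps which extractor stages contribute feature maps
#'   (1-based); default: all stages for the random pyramid, stages 2-4 for
#'   the named topologies.
#' @param feature_distance `"L2"` (mean squared feature difference,
#'   normalized by the target feature energy) or `"L1"`.
#' @param weights_source `"seeded_random"` or `"pretrained_file"`.
#' @param weights_file RDS file holding the extractor convolution kernels
#'   (list of matrices in stage order), required when
#'   `weights_source = "pretrained_file"`.
#' @param pixel_weight optional weight of an auxiliary pixel MSE term added
#'   to the perceptual loss (default 0: perceptual only).
#' @param input_norm perceptual only: standardize inputs by the target
#'   statistics of the whole batch (`"batch"`, default — keeps per-example
#'   loss weights comparable) or of each image (`"image"`).
#' @param data_range,ssim_window,ssim_sigma,ms_scales SSIM-family settings.
#' @param seed seed for random extractor weights.
#' @return object of class `loss_spec`.
#' @export
loss_spec <- function(kind = c("perceptual", "mse", "mae", "ssim", "ms_ssim"),
                      extractor = "random_pyramid", layer_taps = NULL,
                      feature_distance = c("L2", "L1"),
                      weights_source = c("seeded_random", "pretrained_file"),
                      weights_file = NULL, pixel_weight = 0,
                      input_norm = c("batch", "image"),
                      data_range = 1, ssim_window = 11, ssim_sigma = 1.5,
                      ms_scales = 5, seed = 7) {
  input_norm <- match.arg(input_norm)
  kind <- match.arg(kind)
  feature_distance <- match.arg(feature_distance)
  weights_source <- match.arg(weights_source)
  if (kind == "perceptual") {
    if (!extractor %in% names(extractor_plans))
      stopf("unknown extractor '%s'", extractor)
    if (weights_source == "pretrained_file" &&
        (is.null(weights_file) || !file.exists(weights_file)))
      stopf("weights_source = 'pretrained_file' but no weights file found")
    if (!is.null(layer_taps)) {
      ns <- length(extractor_plans[[extractor]]$nconv)
      if (any(layer_taps < 1 | layer_taps > ns))
        stopf("layer_taps must be stage numbers in 1..%d", ns)
    }
  }
  structure(list(kind = kind, extractor = extractor, layer_taps = layer_taps,
                 feature_distance = feature_distance,
                 weights_source = weights_source, weights_file = weights_file,
                 pixel_weight = pixel_weight, input_norm = input_norm,
                 data_range = data_range,
                 ssim_window = ssim_window, ssim_sigma = ssim_sigma,
                 ms_scales = ms_scales, seed = as.integer(seed),
                 env = new.env(parent = emptyenv())),
            class = "loss_spec")
}

#' @export
print.loss_spec <- function(x, ...) {
  if (x$kind == "perceptual")
    cat(sprintf("perceptual loss (%s, %s weights, %s feature distance)\n",
                x$extractor, x$weights_source, x$feature_distance))
  else cat(sprintf("%s loss\n", x$kind))
  invisible(x)
}

get_extractor <- function(spec, H, W) {
  key <- sprintf("%dx%d", H, W)
  cached <- spec$env[[key]]
  if (!is.null(cached) && cpp_ptr_valid(cached)) return(cached)
  plan <- extractor_plans[[spec$extractor]]
  taps <- if (is.null(spec$layer_taps)) plan$taps else as.integer(spec$layer_taps) - 1L
  ptr <- cpp_pyr_create(plan$nconv, plan$chan, taps, H, W, plan$act, spec$seed)
  if (spec$weights_source == "pretrained_file") {
    if (is.null(spec$weights_file) || !file.exists(spec$weights_file))
      stopf("missing pretrained extractor weights file")
    cpp_pyr_set_weights(ptr, readRDS(spec$weights_file))
  }
  spec$env[[key]] <- ptr
  ptr
}

perceptual_loss <- function(spec, preds, trues, want_grad) {
  H <- nrow(preds[[1]]); W <- ncol(preds[[1]]); N <- length(preds)
  ptr <- get_extractor(spec, H, W)
  # standardize both images by the TARGET's statistics (kept constant in
  # the gradient): this retains sensitivity to the predicted noise's
  # overall scale, which the residual subtraction relies on.  Batch-level
  # statistics (default) keep the per-example loss weights comparable;
  # per-image statistics would up-weight examples with faint noise.
  sds <- numeric(N)
  if (identical(spec$input_norm, "image")) {
    for (i in seq_len(N)) {
      m <- mean(trues[[i]])
      s <- sqrt(mean((trues[[i]] - m)^2)); s <- max(s, 1e-6)
      sds[i] <- s
      preds[[i]] <- (preds[[i]] - m) / s
      trues[[i]] <- (trues[[i]] - m) / s
    }
  } else {
    tv <- unlist(trues)
    m <- mean(tv)
    s <- max(sqrt(mean((tv - m)^2)), 1e-6)
    sds[] <- s
    for (i in seq_len(N)) {
      preds[[i]] <- (preds[[i]] - m) / s
      trues[[i]] <- (trues[[i]] - m) / s
    }
  }
  r <- cpp_pyr_loss(ptr, imgs_to_vec(preds), imgs_to_vec(trues), N, want_grad,
                    if (spec$feature_distance == "L1") 1L else 2L)
  if (!want_grad) return(list(value = r$value))
  g <- vec_to_imgs(r$grad, H, W, N)
  for (i in seq_len(N)) g[[i]] <- g[[i]] / sds[i]
  list(value = r$value, grad = g)
}

#' Evaluate a loss module on predicted vs. actual noise images
#'
#' All losses are nonnegative and zero when the inputs are identical (for
#' the SSIM variants, on images with nonzero variance).  With
#' `grad = TRUE` the result carries a `"gradient"` attribute holding the
#' derivative with respect to the predicted noise, enabling gradient
#' descent through any module.
#'
#' @param spec a [loss_spec()].
#' @param predicted_noise,true_noise matrices, 3-d arrays or lists of
#'   matrices of identical shapes.
#' @param grad also compute the gradient with respect to `predicted_noise`.
#' @return scalar loss; with `grad = TRUE`, the `"gradient"` attribute is a
#'   list of matrices (one per image).
#' @export
loss_value <- function(spec, predicted_noise, true_noise, grad = FALSE) {
  if (!inherits(spec, "loss_spec")) stopf("spec must be a loss_spec")
  preds <- as_image_list(predicted_noise)
  trues <- as_image_list(true_noise)
  if (length(preds) != length(trues)) stopf("batch sizes differ")
  for (i in seq_along(preds)) check_same_shape(preds[[i]], trues[[i]])
  N <- length(preds)
  res <- switch(spec$kind,
    mse = {
      gs <- vector("list", N); v <- 0
      npx <- length(preds[[1]]) * N
      for (i in seq_len(N)) {
        d <- preds[[i]] - trues[[i]]
        v <- v + sum(d^2) / npx
        if (grad) gs[[i]] <- 2 * d / npx
      }
      list(value = v, grad = gs)
    },
    mae = {
      gs <- vector("list", N); v <- 0
      npx <- length(preds[[1]]) * N
      for (i in seq_len(N)) {
        d <- preds[[i]] - trues[[i]]
        v <- v + sum(abs(d)) / npx
        if (grad) gs[[i]] <- sign(d) / npx
      }
      list(value = v, grad = gs)
    },
    ssim = {
      gs <- vector("list", N); v <- 0
      for (i in seq_len(N)) {
        if (grad) {
          r <- ssim_with_grad(trues[[i]], preds[[i]], spec$data_range,
                              spec$ssim_window, spec$ssim_sigma)
          gs[[i]] <- -r$grad / N
          v <- v + (1 - r$value) / N
        } else {
          v <- v + (1 - ssim(trues[[i]], preds[[i]], spec$data_range,
                             spec$ssim_window, spec$ssim_sigma)) / N
        }
      }
      list(value = v, grad = gs)
    },
    ms_ssim = {
      gs <- vector("list", N); v <- 0
      for (i in seq_len(N)) {
        r <- ms_ssim_with_grad(trues[[i]], preds[[i]], spec$data_range,
                               spec$ssim_window, spec$ssim_sigma,
                               spec$ms_scales, want_grad = grad)
        if (grad) gs[[i]] <- -r$grad / N
        v <- v + (1 - r$value) / N
      }
      list(value = v, grad = gs)
    },
    perceptual = {
      r <- perceptual_loss(spec, preds, trues, grad)
      if (spec$pixel_weight > 0) {
        npx <- length(preds[[1]]) * N
        for (i in seq_len(N)) {
          d <- preds[[i]] - trues[[i]]
          r$value <- r$value + spec$pixel_weight * sum(d^2) / npx
          if (grad) r$grad[[i]] <- r$grad[[i]] + spec$pixel_weight * 2 * d / npx
        }
      }
      r
    })
  out <- res$value
  if (grad) attr(out, "gradient") <- res$grad
  out
}
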