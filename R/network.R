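# Denoising network architectures.
#
# One code path covers both models: the squeeze-and-excitation U-Net
# (SE blocks + Mish activations) and the BatchNorm UNet baseline
# (leaky-ReLU, no SE), selected purely through the configuration.  Both map
# a noisy image to a predicted noise-artifact image of identical shape
# (residual-output convention): the network estimates the noise component,
# never the clean image.

#' Mish activation
#'
#' `mish(x) = x * tanh(softplus(x))` with an overflow-safe softplus.
#'
#' @param x numeric vector, matrix or array.
#' @return same shape as `x`.
#' @export
mish <- function(x) {
  sp <- ifelse(x > 20, x, ifelse(x < -20, exp(x), log1p(exp(x))))
  x * tanh(sp)
}

#' Network architecture settings
#'
#' The defaults describe the squeeze-and-excitation variant; setting
#' `activation = "leaky_relu"` and `use_se = FALSE` reproduces the BatchNorm
#' UNet baseline exactly (same code path, different configuration).  Channel
#' counts double at each encoder level.
#'
#' @param depth number of encoder levels (the deepest level is the
#'   bottleneck).
#' @param base_channels channels at the first level.
#' @param se_reduction squeeze-and-excitation bottleneck reduction ratio `r`
#'   (>= 1 and <= `base_channels`).
#' @param activation `"mish"` or `"leaky_relu"` (negative slope 0.01).
#' @param use_se whether SE recalibration blocks are appended to every
#'   encoder/decoder block.
#' @param input_size image side length in pixels; must be divisible by
#'   `2^depth`.
#' @export
network_config <- function(depth = 4, base_channels = 32, se_reduction = 8,
                           activation = c("mish", "leaky_relu"),
                           use_se = TRUE, input_size = 128) {
  activation <- match.arg(activation)
  if (depth < 1) stopf("depth must be >= 1")
  if (base_channels < 1) stopf("base_channels must be >= 1")
  if (se_reduction < 1 || se_reduction > base_channels)
    stopf("se_reduction must be in [1, base_channels]")
  if (input_size %% (2^depth) != 0)
    stopf("input_size (%d) must be divisible by 2^depth = %d", input_size, 2^depth)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 se_reduction = as.integer(se_reduction),
                 activation = activation, use_se = isTRUE(use_se),
                 input_size = as.integer(input_size)),
            class = "network_config")
}

act_code <- function(activation) switch(activation, leaky_relu = 0L, mish = 1L)

new_net_ptr <- function(config, seed) {
  cpp_unet_create(config$depth, config$base_channels, config$input_size,
                  config$input_size, act_code(config$activation),
                  config$use_se, config$se_reduction, as.integer(seed))
}

#' Build a denoising network
#'
#' Instantiates the U-Net described by `config`: per level two 3x3
#' convolutions each followed by batch normalization and the configured
#' activation (an SE block appended when `use_se`), 2x2 max-pool
#' downsampling, transposed-convolution upsampling with skip concatenation,
#' and a final linear 1-channel 1x1 convolution (no activation — noise
#' residuals may be signed).  Weights use Kaiming fan-in initialization from
#' the given seed.
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `oa_unet`.
#' @export
build_network <- function(config, seed = 1) {
  if (!inherits(config, "network_config")) stopf("config must be a network_config")
  env <- new.env(parent = emptyenv())
  env$ptr <- new_net_ptr(config, seed)
  net <- structure(list(config = config, seed = as.integer(seed), env = env),
                   class = "oa_unet")
  net$n_params <- cpp_unet_nparams(env$ptr)
  net
}

# re-create the C++ model if the external pointer did not survive
# serialization; restores stored weights when available
net_ptr <- function(net) {
  env <- net$env
  if (is.null(env$ptr) || !cpp_ptr_valid(env$ptr)) {
    env$ptr <- new_net_ptr(net$config, net$seed)
    if (!is.null(env$state)) cpp_unet_set_state(env$ptr, env$state)
  }
  env$ptr
}

net_snapshot <- function(net) {
  net$env$state <- cpp_unet_get_state(net_ptr(net))
  invisible(net)
}

#' Number of trainable parameters of a network
#' @param net an `oa_unet`.
#' @export
param_count <- function(net) cpp_unet_nparams(net_ptr(net))

#' Run the network on a batch of images
#'
#' @param object an `oa_unet`.
#' @param newdata matrix, 3-d array or list of matrices, each
#'   `input_size x input_size`.
#' @param training evaluate in training mode (batch statistics) instead of
#'   inference mode (running statistics).  Inference mode is deterministic
#'   for fixed weights.
#' @param ... unused.
#' @return predicted noise image(s), same container kind as the input.
#' @export
predict.oa_unet <- function(object, newdata, training = FALSE, ...) {
  imgs <- as_image_list(newdata)
  H <- object$config$input_size
  for (m in imgs)
    if (!all(dim(m) == c(H, H)))
      stopf("input images must be %dx%d for this network", H, H)
  v <- cpp_unet_forward(net_ptr(object), imgs_to_vec(imgs), length(imgs), training)
  out <- vec_to_imgs(v, H, H, length(imgs))
  if (is.matrix(newdata)) out[[1]] else out
}

#' @export
print.oa_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s: depth %d, base channels %d, activation %s%s\n",
              if (cfg$use_se) "SE-UNet" else "BatchNorm UNet",
              cfg$depth, cfg$base_channels, cfg$activation,
              if (cfg$use_se) sprintf(", SE reduction %d", cfg$se_reduction) else ""))
  cat(sprintf("  input %dx%d, %s trainable parameters\n", cfg$input_size,
              cfg$input_size, format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Squeeze-and-excitation channel recalibration (reference implementation)
#'
#' Squeeze: per-channel global average.  Excitation: two affine layers
#' (channels -> channels/r -> channels), ReLU between them, sigmoid gate.
#' The input feature map is rescaled per channel by the gate, so the output
#' shape equals the input shape and all gate values lie strictly in (0, 1).
#' This standalone function documents and tests the block's semantics; the
#' network uses an equivalent compiled implementation.
#'
#' @param f feature map array `(H, W, C)`.
#' @param r reduction ratio; must not exceed the channel count.
#' @param weights optional list `W1 (C x C/r)`, `b1`, `W2 (C/r x C)`, `b2`;
#'   seeded-random by default.
#' @param seed seed for the default random weights.
#' @return list with `out` (recalibrated map) and `gate` (length-C vector).
#' @export
se_block <- function(f, r, weights = NULL, seed = 1) {
  if (!is.array(f) || length(dim(f)) != 3) stopf("f must be an (H, W, C) array")
  C <- dim(f)[3]
  if (r > C) stopf("reduction ratio r exceeds channel count")
  Cr <- max(1L, C %/% r)
  if (is.null(weights)) {
    weights <- with_seed(seed, list(
      W1 = matrix(rnorm(C * Cr, 0, sqrt(2 / C)), C, Cr), b1 = numeric(Cr),
      W2 = matrix(rnorm(Cr * C, 0, sqrt(2 / Cr)), Cr, C), b2 = numeric(C)))
  }
  z <- apply(f, 3, mean)
  a1 <- drop(z %*% weights$W1) + weights$b1
  h <- pmax(a1, 0)
  a2 <- drop(h %*% weights$W2) + weights$b2
  gate <- 1 / (1 + exp(-a2))
  out <- f
  for (c in seq_len(C)) out[, , c] <- f[, , c] * gate[c]
  list(out = out, gate = gate)
}

#' Closed-form trainable-parameter count for a network configuration
#'
#' Sums the layer shapes implied by the configuration: convolution kernels,
#' batch-norm scale/shift, SE excitation weights, transposed-convolution
#' kernels and the final projection.  Convolutions followed by batch
#' normalization carry no bias (the shift absorbs it).
#'
#' @param config a [network_config()].
#' @export
param_count_formula <- function(config) {
  d <- config$depth; b <- config$base_channels
  ch <- b * 2^(0:(d - 1))
  conv_bn <- function(cin, cout) cin * 9 * cout + 2 * cout
  se <- function(c) {
    cr <- max(1, c %/% config$se_reduction)
    c * cr + cr + cr * c + c
  }
  total <- 0
  for (i in seq_len(d)) {
    cin <- if (i == 1) 1 else ch[i - 1]
    total <- total + conv_bn(cin, ch[i]) + conv_bn(ch[i], ch[i])
    if (config$use_se) total <- total + se(ch[i])
  }
  if (d > 1) for (i in seq_len(d - 1)) {
    total <- total + ch[i + 1] * ch[i] * 4 + ch[i]          # transposed conv
    total <- total + conv_bn(2 * ch[i], ch[i]) + conv_bn(ch[i], ch[i])
    if (config$use_se) total <- total + se(ch[i])
  }
  total + b + 1                                             # final 1x1
}
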