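# Residual-learning training and the inference path:
# predict the noise, subtract it, restore brightness/contrast.
#
# The training target for a triplet is w * I_noise — the noise component as
# it is actually present in the mixture — so that under a perfect predictor
# the residual subtraction recovers (1 - w) * I_signal exactly; the pure
# noise image is the w = 1 special case.  This choice keeps the subtraction
# algebra exact and directly testable.

#' Training settings
#'
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size images per gradient step (>= 1).
#' @param learning_rate Adam base learning rate; decays along a cosine
#'   schedule over the epochs when `lr_decay = "cosine"`.
#' @param optimizer only `"adam"` is provided.
#' @param seed master seed: weight init, shuffling and any stochastic loss
#'   component all derive from it.
#' @param patience early stopping: stop when validation loss has not
#'   improved for this many epochs; the best-validation weights are restored
#'   either way.
#' @param checkpoint_every if > 0 and `checkpoint_dir` is set, write a
#'   checkpoint every so many epochs.
#' @param checkpoint_dir directory for checkpoints (optional).
#' @param lr_decay `"cosine"` or `"none"`.
#' @export
trainer_config <- function(epochs = 30, batch_size = 8, learning_rate = 1e-3,
                           optimizer = "adam", seed = 1, patience = 10,
                           checkpoint_every = 0, checkpoint_dir = NULL,
                           lr_decay = c("cosine", "none")) {
  if (epochs < 1) stopf("epochs must be >= 1")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  if (!identical(optimizer, "adam")) stopf("only the adam optimizer is provided")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), patience = as.integer(patience),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir,
                 lr_decay = match.arg(lr_decay)),
            class = "trainer_config")
}

triplets_of <- function(x, part) {
  if (inherits(x, "oa_dataset")) return(x[[part]])
  if (inherits(x, "oa_triplet")) return(list(x))
  x
}

batch_loss_eval <- function(net, spec, triplets, batch_size) {
  total <- 0; n <- 0
  for (b in split(seq_along(triplets),
                  ceiling(seq_along(triplets) / batch_size))) {
    mixed <- lapply(triplets[b], function(t) t$mixed)
    target <- lapply(triplets[b], function(t) t$w * t$noise)
    pred <- predict.oa_unet(structure(net, class = "oa_unet"), mixed,
                            training = FALSE)
    total <- total + as.numeric(loss_value(spec, pred, target)) * length(b)
    n <- n + length(b)
  }
  total / n
}

#' Fit a residual-noise denoiser
#'
#' Trains a network to predict the noise component `w * I_noise` of each
#' mixed training image, minimizing the configured loss-evaluation module.
#' Per-epoch training and validation losses are recorded, the
#' best-validation weights are checkpointed and restored, and the whole run
#' is a deterministic function of the configurations and the seed.  A
#' non-finite loss aborts with an error of class `oa_divergence` carrying
#' the history so far.
#'
#' @param train training data: an `oa_dataset` (its `$train` part is used)
#'   or a list of triplets from [build_dataset()].
#' @param val validation triplets; defaults to the dataset's `$val` part.
#' @param network a [network_config()]; its `input_size` is aligned to the
#'   data automatically.
#' @param loss a [loss_spec()].
#' @param control a [trainer_config()].
#' @param verbose print per-epoch progress.
#' @return an object of class `oa_denoiser` with, among others, a `history`
#'   data frame and the trained weights; see [predict.oa_denoiser()].
#' @export
fit_denoiser <- function(train, val = NULL,
                         network = network_config(depth = 3, base_channels = 16,
                                                  input_size = 64),
                         loss = loss_spec("perceptual"),
                         control = trainer_config(), verbose = FALSE) {
  tr <- triplets_of(train, "train")
  if (is.null(val) && inherits(train, "oa_dataset")) val <- train$val
  va <- if (is.null(val)) list() else triplets_of(val, "val")
  if (length(tr) == 0) stopf("empty training set")
  H <- nrow(tr[[1]]$signal)
  if (network$input_size != H) {
    network <- network_config(network$depth, network$base_channels,
                              network$se_reduction, network$activation,
                              network$use_se, H)
  }
  net <- build_network(network, seed = derive_seed(control$seed, "init"))
  ptr <- net_ptr(net)

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  best_val <- Inf; best_state <- NULL; best_epoch <- NA_integer_
  stale <- 0L
  abort_diverged <- function() {
    cond <- structure(class = c("oa_divergence", "error", "condition"),
                      list(message = "training diverged (non-finite loss)",
                           call = NULL, history = history))
    stop(cond)
  }

  for (epoch in seq_len(control$epochs)) {
    lr <- if (control$lr_decay == "cosine")
      control$learning_rate * 0.5 * (1 + cos(pi * (epoch - 1) / control$epochs))
    else control$learning_rate
    ord <- with_seed(derive_seed(control$seed, paste0("shuffle:", epoch)),
                     sample.int(length(tr)))
    ep_loss <- 0; nb <- 0
    for (b in split(ord, ceiling(seq_along(ord) / control$batch_size))) {
      mixed <- lapply(tr[b], function(t) t$mixed)
      target <- lapply(tr[b], function(t) t$w * t$noise)
      v <- cpp_unet_forward(ptr, imgs_to_vec(mixed), length(b), TRUE)
      pred <- vec_to_imgs(v, H, H, length(b))
      lv <- loss_value(loss, pred, target, grad = TRUE)
      if (!is.finite(lv)) abort_diverged()
      gvec <- imgs_to_vec(attr(lv, "gradient"))
      cpp_unet_zero_grad(ptr)
      cpp_unet_backward(ptr, gvec)
      cpp_unet_step(ptr, lr, 0.9, 0.999, 1e-8)
      ep_loss <- ep_loss + as.numeric(lv); nb <- nb + 1
    }
    ep_loss <- ep_loss / nb
    vl <- if (length(va)) batch_loss_eval(net, loss, va, control$batch_size) else NA_real_
    if (!is.finite(ep_loss) || (length(va) && !is.finite(vl))) abort_diverged()
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_loss = vl, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %s  lr %.2e", epoch, ep_loss,
                      ifelse(is.na(vl), "-", sprintf("%.5f", vl)), lr))
    crit <- if (length(va)) vl else ep_loss
    if (crit < best_val - 1e-12) {
      best_val <- crit; best_state <- cpp_unet_get_state(ptr)
      best_epoch <- epoch; stale <- 0L
    } else stale <- stale + 1L
    if (control$checkpoint_every > 0 && !is.null(control$checkpoint_dir) &&
        epoch %% control$checkpoint_every == 0) {
      dir.create(control$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(cpp_unet_get_state(ptr),
              file.path(control$checkpoint_dir, sprintf("epoch%03d.rds", epoch)))
    }
    if (stale >= control$patience) break
  }
  if (!is.null(best_state)) cpp_unet_set_state(ptr, best_state)
  net$env$state <- cpp_unet_get_state(ptr)

  structure(list(network = network, config = network, loss = loss,
                 control = control,
                 history = history, best_epoch = best_epoch,
                 n_params = net$n_params, input_size = H,
                 seed = net$seed, env = net$env),
            class = c("oa_denoiser", "oa_unet"))
}

#' Global brightness/contrast restoration (BCR)
#'
#' After noise subtraction the restored images are typically very dark; this
#' global affine intensity remap subtracts the 1st percentile, divides by
#' the 99th-1st percentile span and clips to `[0, 1]`.  It is invariant to
#' positive affine transforms of the input; constant images map to zeros.
#'
#' @param img numeric matrix.
#' @param probs lower/upper percentile pair.
#' @examples
#' dark <- 0.3 * make_phantom(phantom_config(grid_size = 64, seed = 1))
#' bright <- bcr(dark)
#' range(bright)
#' @export
bcr <- function(img, probs = c(0.01, 0.99)) {
  check_image(img)
  q <- stats::quantile(img, probs, names = FALSE)
  if (q[2] - q[1] <= 0) return(array(0, dim(img)))
  clip01((img - q[1]) / (q[2] - q[1]))
}

new_denoising_result <- function(noisy, predicted, apply_bcr = TRUE) {
  raw <- noisy - predicted
  structure(list(noisy = noisy, predicted_noise = predicted,
                 restored_raw = raw,
                 restored = if (apply_bcr) bcr(raw) else clip01(raw)),
            class = "oa_denoised")
}

#' Denoise an image by residual subtraction
#'
#' Runs the model on the noisy input to infer the noise-artifact image, then
#' subtracts: `restored_raw = noisy - predicted_noise` (an exact identity,
#' kept bit-exact), followed by [bcr()].  `model` may be a fitted
#' `oa_denoiser` or any function mapping an image matrix to a predicted
#' noise matrix (useful for oracle predictors in tests).
#'
#' @param model an `oa_denoiser` or a function.
#' @param noisy numeric matrix (or list/array of images).
#' @param apply_bcr apply brightness/contrast restoration to the result.
#' @return an `oa_denoised` result (list of them for multiple images) with
#'   fields `noisy`, `predicted_noise`, `restored_raw`, `restored`.
#' @export
denoise <- function(model, noisy, apply_bcr = TRUE) {
  imgs <- as_image_list(noisy)
  preds <- if (is.function(model)) lapply(imgs, model)
  else predict.oa_unet(model, imgs, training = FALSE)
  for (i in seq_along(imgs)) check_same_shape(imgs[[i]], preds[[i]])
  out <- mapply(new_denoising_result, imgs, preds,
                MoreArgs = list(apply_bcr = apply_bcr), SIMPLIFY = FALSE)
  if (is.matrix(noisy)) out[[1]] else out
}

#' Predict method for fitted denoisers
#'
#' @param object an `oa_denoiser`.
#' @param newdata image matrix, array, list of matrices, or triplet(s).
#' @param apply_bcr apply brightness/contrast restoration.
#' @param ... unused.
#' @return `oa_denoised` result(s).
#' @export
predict.oa_denoiser <- function(object, newdata, apply_bcr = TRUE, ...) {
  if (inherits(newdata, "oa_triplet")) newdata <- newdata$mixed
  if (is.list(newdata) && length(newdata) && inherits(newdata[[1]], "oa_triplet"))
    newdata <- lapply(newdata, function(t) t$mixed)
  denoise(object, newdata, apply_bcr = apply_bcr)
}

#' Residuals of a fitted denoiser
#'
#' For a residual-learning denoiser the natural residual is the inferred
#' noise-artifact image itself.
#'
#' @param object an `oa_denoiser`.
#' @param newdata images or triplets to infer noise for.
#' @param ... unused.
#' @export
residuals.oa_denoiser <- function(object, newdata, ...) {
  if (inherits(newdata, "oa_triplet")) newdata <- newdata$mixed
  if (is.list(newdata) && length(newdata) && inherits(newdata[[1]], "oa_triplet"))
    newdata <- lapply(newdata, function(t) t$mixed)
  predict.oa_unet(object, newdata, training = FALSE)
}

#' @export
coef.oa_denoiser <- function(object, ...) {
  st <- object$env$state
  if (is.null(st)) st <- cpp_unet_get_state(net_ptr(object))
  st$params
}

#' @export
print.oa_denoiser <- function(x, ...) {
  cfg <- x$network
  cat(sprintf("Residual-noise denoiser (%s, depth %d, base %d, %s loss)\n",
              if (cfg$use_se) "SE-UNet" else "BatchNorm UNet", cfg$depth,
              cfg$base_channels, x$loss$kind))
  cat(sprintf("  %s parameters; trained %d epoch(s), best at epoch %s\n",
              format(x$n_params, big.mark = ","), nrow(x$history),
              ifelse(is.na(x$best_epoch), "-", x$best_epoch)))
  h <- x$history
  if (nrow(h))
    cat(sprintf("  final train loss %.5f%s\n", h$train_loss[nrow(h)],
                if (!all(is.na(h$val_loss)))
                  sprintf(", val loss %.5f", h$val_loss[nrow(h)]) else ""))
  invisible(x)
}

#' @export
summary.oa_denoiser <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  train loss: first %.5f, min %.5f\n", h$train_loss[1],
              min(h$train_loss)))
  if (!all(is.na(h$val_loss)))
    cat(sprintf("  val loss:   first %.5f, min %.5f (epoch %d)\n",
                h$val_loss[1], min(h$val_loss, na.rm = TRUE),
                h$epoch[which.min(h$val_loss)]))
  invisible(object)
}

#' Plot training history
#'
#' @param x an `oa_denoiser`.
#' @param ... passed to `plot`.
#' @export
plot.oa_denoiser <- function(x, ...) {
  h <- x$history
  rng <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = rng, ...)
  if (!all(is.na(h$val_loss))) {
    lines(h$epoch, h$val_loss, lty = 2)
    legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' Save / load a fitted denoiser
#'
#' The weights are stored in an RDS file together with a JSON sidecar
#' recording the architecture and training provenance.
#'
#' @param model an `oa_denoiser`.
#' @param path RDS path; the sidecar gets the extension `.json`.
#' @export
save_denoiser <- function(model, path) {
  if (is.null(model$env$state)) net_snapshot(model)
  obj <- unclass(model)
  obj$state <- model$env$state
  obj$env <- NULL
  obj$loss$env <- NULL
  saveRDS(obj, path)
  side <- sub("\\.rds$", ".json", path, ignore.case = TRUE)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(list(
    network = model$network[c("depth", "base_channels", "se_reduction",
                              "activation", "use_se", "input_size")],
    loss_kind = model$loss$kind, epochs_trained = nrow(model$history),
    best_epoch = model$best_epoch, n_params = model$n_params,
    seed = model$control$seed), side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_denoiser
#' @param path RDS path written by [save_denoiser()].
#' @export
load_denoiser <- function(path) {
  obj <- readRDS(path)
  env <- new.env(parent = emptyenv())
  env$state <- obj$state
  obj$state <- NULL
  obj$env <- env
  obj$loss$env <- new.env(parent = emptyenv())
  class(obj$loss) <- "loss_spec"
  structure(obj, class = c("oa_denoiser", "oa_unet"))
}
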