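# Loss-evaluation-module comparison harness.
#
# To rank loss modules without confounding from a large model, a simpler
# BatchNorm UNet is trained once per candidate module under identical seeds
# and hyperparameters, and each trained model is scored by the VIF of its
# restored test images against the clean reference on the fixed noise-level
# grid w in {0.3, 0.5, 0.7}.

#' Compare loss-evaluation modules under identical training conditions
#'
#' @param data an `oa_dataset` with train/val/test parts.
#' @param network a [network_config()]; the default comparison model is the
#'   BatchNorm UNet baseline.
#' @param specs named list of [loss_spec()] candidates (at least 2).
#' @param control a [trainer_config()] shared by all candidates.
#' @param vif_cfg a [vif_config()] used for scoring.
#' @param apply_bcr score BCR-restored images (default) rather than raw
#'   subtractions.
#' @param verbose print progress.
#' @return object of class `oa_loss_comparison`: data frame with one row per
#'   (spec, w): mean VIF, sd and n, plus a `models` attribute.
#' @export
compare_loss_modules <- function(data, network, specs,
                                 control = trainer_config(),
                                 vif_cfg = vif_config(), apply_bcr = TRUE,
                                 verbose = FALSE) {
  if (!inherits(data, "oa_dataset")) stopf("data must be an oa_dataset")
  if (length(specs) < 2) stopf("need at least 2 loss specs to compare")
  if (is.null(names(specs)) || any(names(specs) == ""))
    names(specs) <- vapply(specs, function(s) s$kind, character(1))
  rows <- list(); models <- list()
  for (nm in names(specs)) {
    fit <- tryCatch(
      fit_denoiser(data$train, data$val, network = network, loss = specs[[nm]],
                   control = control, verbose = verbose),
      error = function(e) stopf("training failed for loss spec '%s': %s", nm,
                                conditionMessage(e)))
    models[[nm]] <- fit
    ws <- vapply(data$test, function(t) t$w, numeric(1))
    # the restored image lives on the BCR-normalized intensity scale, so the
    # reference is normalized the same way before scoring
    scores <- vapply(data$test, function(t) {
      r <- denoise(fit, t$mixed, apply_bcr = apply_bcr)
      ref <- if (apply_bcr) bcr(t$signal) else t$signal
      vif(ref, r$restored, vif_cfg)
    }, numeric(1))
    for (w in sort(unique(ws))) {
      s <- scores[ws == w]
      rows[[length(rows) + 1]] <- data.frame(
        spec = nm, w = w, mean_vif = mean(s),
        sd_vif = if (length(s) > 1) stats::sd(s) else 0, n = length(s))
    }
    if (verbose) message(sprintf("[%s] mean VIF %.4f", nm, mean(scores)))
  }
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  class(out) <- c("oa_loss_comparison", "data.frame")
  out
}

#' @export
print.oa_loss_comparison <- function(x, ...) {
  cat("Loss-evaluation-module comparison (mean VIF by noise level)\n")
  tab <- stats::reshape(as.data.frame(x)[c("spec", "w", "mean_vif")],
                        idvar = "spec", timevar = "w", direction = "wide")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a loss comparison to CSV and JSON
#' @param x an `oa_loss_comparison`.
#' @param csv_path,json_path output paths (either may be NULL).
#' @export
write_loss_comparison <- function(x, csv_path = NULL, json_path = NULL) {
  df <- as.data.frame(x)
  if (!is.null(csv_path)) write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(df, json_path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}
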