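#' Fit an apnea classifier to labeled windows
#'
#' Front door of the package: takes preprocessed, labeled segment
#' windows, builds the stacked convolutional / bidirectional-GRU network
#' with dot-product attention, and trains it with seeded mini-batch Adam
#' on binary cross-entropy, checkpointing the weights whenever the
#' validation accuracy improves.
#'
#' When no validation set is supplied, `val_fraction` of the *recordings*
#' (not windows) is held out with a seeded assignment; splitting by whole
#' recording avoids leakage between overlapping five-minute context
#' windows of the same record. If all windows come from one recording,
#' the split falls back to window level.
#'
#' Channel normalization (per-channel z-score) is computed on the
#' training windows and stored with the model, so inference on new data
#' is self-contained.
#'
#' @param windows Non-empty list of [segment_window()] objects.
#' @param val Optional validation window list; default `NULL` splits from
#'   `windows`.
#' @param spec A [model_spec()] describing the architecture.
#' @param control A [train_control()] with the optimisation settings.
#' @param oversample Balance the training classes by duplicating the
#'   minority class before training (default FALSE).
#' @return An object of class `apnea_net`: the trained `model`, training
#'   `history`, `best_val_accuracy`, `spec`, `control`, window counts and
#'   the matched call. Methods: [print.apnea_net()],
#'   [summary.apnea_net()], [predict.apnea_net()], [plot.apnea_net()],
#'   [coef.apnea_net()].
#' @examples
#' \donttest{
#' dir <- file.path(tempdir(), "sim")
#' generate_dataset(2, dir, seed = 7, duration_s = 600)
#' man <- read_manifest(dir)
#' wins <- list()
#' for (rec in man$records) {
#'   ecg <- read_wfdb_record(file.path(dir, rec$record_id))
#'   lab <- read_apnea_minute_labels(
#'     file.path(dir, paste0(rec$record_id, ".apn.txt")))
#'   wins <- c(wins, preprocess_record(ecg, lab))
#' }
#' fit <- apnea_net(wins, spec = model_spec(n_blocks = 1, filters = 4,
#'                                          units = 4),
#'                  control = train_control(epochs = 1, batch_size = 8,
#'                                          seed = 7))
#' predict(fit, wins[1:3])
#' }
#' @export
apnea_net <- function(windows, val = NULL, spec = model_spec(),
                      control = train_control(), oversample = FALSE) {
  cl <- match.call()
  if (!length(windows)) stop("`windows` is empty", call. = FALSE)
  set.seed(control$seed)
  if (is.null(val)) {
    ids <- vapply(windows, `[[`, character(1), "record_id")
    uids <- unique(ids)
    if (length(uids) > 1L) {
      n_val <- max(1L, round(control$val_fraction * length(uids)))
      val_ids <- sample(uids, n_val)
      val <- windows[ids %in% val_ids]
      windows <- windows[!ids %in% val_ids]
    } else {
      n_val <- max(1L, round(control$val_fraction * length(windows)))
      vi <- sample(seq_along(windows), n_val)
      val <- windows[vi]
      windows <- windows[-vi]
    }
    if (!length(windows))
      stop("validation split consumed all training windows",
           call. = FALSE)
  }
  if (oversample)
    windows <- oversample_minority(windows, seed = control$seed)

  batch <- windows_to_batch(windows)
  model <- build_model(spec,
                       input_shape = c(dim(batch$x)[2L],
                                       dim(batch$x)[3L]),
                       seed = control$seed)
  model$normalization <- batch_normalization(batch$x)
  tr <- train(model, batch, val, control)

  structure(list(model = tr$model, history = tr$history,
                 best_val_accuracy = tr$best_val_accuracy,
                 best_epoch = tr$best_epoch,
                 spec = spec, control = control,
                 n_train = length(batch$y),
                 n_val = length(as_batch(val)$y),
                 call = cl),
            class = "apnea_net")
}

#' @export
print.apnea_net <- function(x, ...) {
  cat("Sleep-apnea segment classifier (conv-BiGRU-attention)\n")
  cat(sprintf("  blocks: %d, filters: %d, GRU units: %d, parameters: %s\n",
              x$spec$n_blocks, x$spec$filters, x$spec$units,
              format(x$model$param_count, big.mark = ",")))
  cat(sprintf("  trained %d epoch(s) on %d windows (%d validation)\n",
              nrow(x$history), x$n_train, x$n_val))
  if (is.finite(x$best_val_accuracy))
    cat(sprintf("  best validation accuracy: %.3f (epoch %d)\n",
                x$best_val_accuracy, x$best_epoch))
  invisible(x)
}

#' Summary of a fitted apnea classifier
#'
#' @param object An `apnea_net`.
#' @param ... Unused.
#' @return `object`, invisibly; prints the layer table and training
#'   history.
#' @export
summary.apnea_net <- function(object, ...) {
  print(object)
  cat("\nLayer stack:\n")
  print(model_layer_table(object$model), row.names = FALSE)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' Predict apnea probabilities or classes for new windows
#'
#' @param object A fitted `apnea_net`.
#' @param newdata Window list or batch array.
#' @param type `"prob"` for the two-column probability matrix, `"class"`
#'   for hard 0/1 calls (apneic when the apnea probability is >= 0.5).
#' @param ... Unused.
#' @return A probability matrix (columns `normal`, `sa`) or an integer
#'   vector of 0/1 calls.
#' @export
predict.apnea_net <- function(object, newdata,
                              type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- model_forward(object$model, newdata)
  if (type == "prob") p else as.integer(p[, "sa"] >= 0.5)
}

#' Plot training history
#'
#' Training loss and validation accuracy per epoch.
#'
#' @param x An `apnea_net`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.apnea_net <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot", call. = FALSE)
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training loss", ...)
  graphics::plot(h$epoch, h$val_accuracy, type = "b", pch = 16,
                 xlab = "epoch", ylab = "validation accuracy",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' Extract network weights
#'
#' @param object An `apnea_net`.
#' @param ... Unused.
#' @return The nested list of weight arrays, one entry per layer (NULL
#'   for parameter-free layers).
#' @export
coef.apnea_net <- function(object, ...) {
  net_params(object$model$layers)
}
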