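# Per-segment classification metrics, ROC/AUC, and per-recording
# diagnosis via the apnea-hypopnea index (AHI) with cohort-level MAE and
# Pearson correlation.

#' Confusion-matrix metrics
#'
#' Accuracy, recall (sensitivity), specificity, precision and F1 from the
#' four confusion counts, with the apneic class as positive. Ratios with
#' zero denominators are reported as `NaN`, never coerced to 0.
#'
#' @param tp,fp,tn,fn Nonnegative counts; `tp` may also be a named vector
#'   or list with elements `tp`, `fp`, `tn`, `fn`.
#' @return Named list with `accuracy`, `recall`, `specificity`,
#'   `precision`, `f1` (fractions in [0, 1]).
#' @export
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp) && (is.list(tp) || length(tp) == 4L)) {
    cc <- as.list(tp)
    names(cc) <- tolower(names(cc))
    fp <- cc$fp; tn <- cc$tn; fn <- cc$fn; tp <- cc$tp
  }
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(counts) == 0) stop("no observations", call. = FALSE)
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       recall = recall,
       specificity = tn / (tn + fp),
       precision = precision,
       f1 = 2 * precision * recall / (precision + recall))
}

#' Area under the ROC curve
#'
#' Rank-statistic AUC: the probability that a randomly chosen apneic
#' segment receives a higher score than a randomly chosen normal one,
#' counting ties as one half (equivalent to the normalised Mann-Whitney
#' U statistic, and to trapezoidal integration of the empirical ROC
#' curve).
#'
#' @param scores Numeric scores (higher = more apneic).
#' @param labels Binary labels (0/1); both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)            # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-recording diagnosis from minute predictions
#'
#' Computes the apnea-hypopnea index `AHI = 60 * N / T` from `N` predicted
#' apneic minutes out of `T` evaluated minutes, and calls the recording
#' apneic when AHI is strictly greater than 5 events/hour.
#'
#' @param minute_predictions Binary vector (0/1), one entry per evaluated
#'   minute; must be non-empty.
#' @param record_id Optional identifier.
#' @param ahi_true Optional reference AHI for the recording.
#' @return An object of class `recording_result` with fields `record_id`,
#'   `minute_predictions`, `N`, `T`, `ahi_pred`, `diagnosis`
#'   ("SA"/"normal") and `ahi_true`.
#' @export
evaluate_recording <- function(minute_predictions,
                               record_id = NA_character_,
                               ahi_true = NA_real_) {
  preds <- as.integer(minute_predictions)
  if (!length(preds)) stop("empty prediction vector", call. = FALSE)
  if (!all(preds %in% c(0L, 1L)))
    stop("predictions must be 0/1", call. = FALSE)
  N <- sum(preds)
  T_ <- length(preds)
  ahi <- 60 * N / T_
  structure(list(record_id = as.character(record_id),
                 minute_predictions = preds,
                 N = N, T = T_, ahi_pred = ahi,
                 diagnosis = if (ahi > 5) "SA" else "normal",
                 ahi_true = ahi_true),
            class = "recording_result")
}

#' @export
print.recording_result <- function(x, ...) {
  cat(sprintf("<recording '%s': %d/%d apneic minutes, AHI %.2f -> %s>\n",
              x$record_id, x$N, x$T, x$ahi_pred, x$diagnosis))
  invisible(x)
}

#' Cohort-level AHI agreement
#'
#' Mean absolute error and Pearson correlation between predicted and
#' reference AHI values over a cohort of recordings.
#'
#' @param ahi_pred,ahi_true Numeric vectors of equal length (one entry per
#'   recording), or `ahi_pred` may be a list of `recording_result`
#'   objects carrying `ahi_true`.
#' @return An object of class `cohort_evaluation` with fields `pairs`
#'   (data.frame), `mae` and `corr`. When either vector has zero
#'   variance, `corr` is `NA` with a warning.
#' @export
cohort_mae_corr <- function(ahi_pred, ahi_true = NULL) {
  if (is.null(ahi_true)) {
    stopifnot(is.list(ahi_pred))
    ahi_true <- vapply(ahi_pred, `[[`, numeric(1), "ahi_true")
    ahi_pred <- vapply(ahi_pred, `[[`, numeric(1), "ahi_pred")
  }
  if (length(ahi_pred) != length(ahi_true))
    stop("prediction and reference vectors differ in length",
         call. = FALSE)
  mae <- mean(abs(ahi_pred - ahi_true))
  corr <- if (length(ahi_pred) >= 2 &&
              stats::sd(ahi_pred) > 0 && stats::sd(ahi_true) > 0) {
    stats::cor(ahi_pred, ahi_true)
  } else {
    warning("zero variance in AHI values; correlation undefined",
            call. = FALSE)
    NA_real_
  }
  structure(list(pairs = data.frame(ahi_pred = ahi_pred,
                                    ahi_true = ahi_true),
                 mae = mae, corr = corr),
            class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("<cohort of %d recordings: MAE %.2f, Corr %s>\n",
              nrow(x$pairs), x$mae,
              if (is.na(x$corr)) "NA" else sprintf("%.3f", x$corr)))
  invisible(x)
}

#' Per-segment evaluation of a model
#'
#' Classifies each window (apneic when the softmax apnea probability is
#' at least 0.5, i.e. the argmax class), aggregates confusion counts, and
#' computes the metric set plus AUC.
#'
#' @param object A fitted `apnea_net` (or an `apnea_model` with weights).
#' @param windows Non-empty labeled window set.
#' @return A list with `counts` (named TP/FP/TN/FN vector), `metrics`
#'   (from [confusion_metrics()]), `auc` (NA when only one class is
#'   present), `n`, and the score/label vectors used.
#' @export
evaluate_per_segment <- function(object, windows) {
  batch <- as_batch(windows)
  if (!length(batch$y)) stop("empty window set", call. = FALSE)
  model <- if (inherits(object, "apnea_net")) object$model else object
  p <- model_forward(model, batch$x)
  scores <- p[, "sa"]
  pred <- as.integer(scores >= 0.5)
  y <- batch$y
  counts <- c(tp = sum(pred == 1L & y == 1L),
              fp = sum(pred == 1L & y == 0L),
              tn = sum(pred == 0L & y == 0L),
              fn = sum(pred == 0L & y == 1L))
  auc <- if (length(unique(y)) == 2L) roc_auc(scores, y) else NA_real_
  list(counts = counts, metrics = confusion_metrics(counts),
       auc = auc, n = length(y), scores = scores, labels = y)
}
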