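# Mini-batch training: binary cross-entropy loss, the bias-corrected
# Adam update, a seeded epoch loop with best-on-validation checkpointing,
# minority oversampling, and fine-tuning from pretrained weights.

#' Training configuration
#'
#' @param epochs Number of training epochs (default 40).
#' @param learning_rate Adam step size alpha (default 0.001).
#' @param batch_size Mini-batch size (default 128).
#' @param beta1,beta2 Adam moment decay rates (defaults 0.9, 0.999).
#' @param epsilon Adam denominator offset (default 1e-7).
#' @param seed RNG seed controlling shuffling, dropout and any validation
#'   split (default 1).
#' @param val_fraction Fraction of recordings held out for validation when
#'   no validation set is supplied (default 0.2).
#' @return An object of class `train_control`.
#' @export
train_control <- function(epochs = 40L, learning_rate = 0.001,
                          batch_size = 128L, beta1 = 0.9, beta2 = 0.999,
                          epsilon = 1e-7, seed = 1L,
                          val_fraction = 0.2) {
  if (epochs < 0L) stop("`epochs` must be >= 0", call. = FALSE)
  if (learning_rate <= 0) stop("`learning_rate` must be > 0",
                               call. = FALSE)
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1)
    stop("`beta1` and `beta2` must lie in (0, 1)", call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("`val_fraction` must lie in (0, 1)", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed), val_fraction = val_fraction),
            class = "train_control")
}

#' Binary cross-entropy loss
#'
#' `J = -(1/n) * sum(y * log(yhat) + (1 - y) * log(1 - yhat))`, with the
#' predicted probabilities clipped away from 0 and 1 to avoid infinite
#' logs.
#'
#' @param y Binary labels (0/1).
#' @param yhat Predicted probabilities of the positive class.
#' @param clip Clipping bound (default 1e-7).
#' @return Scalar loss.
#' @export
bce_loss <- function(y, yhat, clip = 1e-7) {
  if (length(y) != length(yhat))
    stop("`y` and `yhat` must have equal length", call. = FALSE)
  yhat <- pmin(pmax(yhat, clip), 1 - clip)
  -mean(y * log(yhat) + (1 - y) * log(1 - yhat))
}

#' One Adam update
#'
#' Bias-corrected Adam on an arbitrary (possibly nested) list of numeric
#' parameter arrays:
#' `m <- beta1 m + (1 - beta1) g`; `v <- beta2 v + (1 - beta2) g^2`;
#' `theta <- theta - alpha * sqrt(1 - beta2^t) / (1 - beta1^t) *
#'  m / (sqrt(v) + epsilon)`.
#'
#' @param params Numeric array or nested list of arrays.
#' @param grads Gradient tree with the same shape as `params`.
#' @param state Optimiser state from a previous call, or `NULL` to start
#'   from zero moments (`m0 = v0 = 0`, `t = 0`).
#' @param control A [train_control()] supplying `learning_rate`, `beta1`,
#'   `beta2` and `epsilon`.
#' @return A list with updated `params` and `state` (fields `m`, `v`,
#'   `t`).
#' @export
adam_update <- function(params, grads, state = NULL,
                        control = train_control()) {
  if (is.null(state))
    state <- list(m = tree_map(function(x) if (is.null(x)) NULL else x * 0,
                               params),
                  v = tree_map(function(x) if (is.null(x)) NULL else x * 0,
                               params),
                  t = 0L)
  t <- state$t + 1L
  b1 <- control$beta1; b2 <- control$beta2
  state$m <- tree_map2(function(m, g) {
    if (is.null(m)) return(NULL)
    b1 * m + (1 - b1) * g
  }, state$m, grads)
  state$v <- tree_map2(function(v, g) {
    if (is.null(v)) return(NULL)
    b2 * v + (1 - b2) * g^2
  }, state$v, grads)
  alpha_t <- control$learning_rate * sqrt(1 - b2^t) / (1 - b1^t)
  params <- tree_map2(function(p, mv) {
    if (is.null(p)) return(NULL)
    p - alpha_t * mv$m / (sqrt(mv$v) + control$epsilon)
  }, params, tree_zip(state$m, state$v))
  state$t <- t
  list(params = params, state = state)
}

# zip two parallel trees into one tree of list(m=, v=) leaves
tree_zip <- function(a, b) {
  if (is.list(a)) return(mapply(tree_zip, a, b, SIMPLIFY = FALSE))
  list(m = a, v = b)
}

# canonicalize a window set into a batch list(x, y, ...)
as_batch <- function(windows) {
  if (is.list(windows) && !is.null(windows$x) && !is.null(windows$y))
    return(windows)
  windows_to_batch(windows)
}

#' Train a model
#'
#' Seeded mini-batch training with Adam on binary cross-entropy. After
#' each epoch the validation accuracy is evaluated in inference mode and
#' the weights are checkpointed whenever it improves (ties keep the
#' earlier checkpoint); the returned model carries the best checkpoint.
#'
#' @param model An `apnea_model` from [build_model()] (its stored channel
#'   normalization, if any, is applied to both sets).
#' @param train_windows,val_windows Non-empty window sets: lists of
#'   [segment_window()] or batches from `windows_to_batch()`.
#' @param control A [train_control()].
#' @return A list of class `apnea_train`: `model` (best weights),
#'   `history` (data.frame with per-epoch `epoch`, `train_loss`,
#'   `val_accuracy`), `best_val_accuracy`, `best_epoch` (0 means the
#'   initial weights were never improved upon).
#' @export
train <- function(model, train_windows, val_windows,
                  control = train_control()) {
  stopifnot(inherits(model, "apnea_model"))
  tr <- as_batch(train_windows)
  va <- as_batch(val_windows)
  if (!length(tr$y) || !length(va$y))
    stop("training and validation sets must be non-empty", call. = FALSE)
  set.seed(control$seed)
  xtr <- apply_normalization(tr$x, model$normalization)
  xva <- apply_normalization(va$x, model$normalization)
  layers <- model$layers
  n <- length(tr$y)
  state <- NULL
  best_params <- net_params(layers)
  best_acc <- -Inf
  best_epoch <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_accuracy = numeric(0))

  for (epoch in seq_len(control$epochs)) {
    idx <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = control$batch_size)) {
      bi <- idx[start:min(start + control$batch_size - 1L, n)]
      xb <- xtr[bi, , , drop = FALSE]
      yb <- tr$y[bi]
      fw <- net_forward(layers, xb, training = TRUE)
      p <- fw$out
      losses <- c(losses, bce_loss(yb, p[, 2L]))
      onehot <- cbind(1 - yb, yb)
      dZ <- (p - onehot) / length(yb)
      grads <- net_backward(layers, fw$caches, dZ)
      upd <- adam_update(net_params(layers), grads, state, control)
      layers <- net_set_params(layers, upd$params)
      state <- upd$state
    }
    pv <- net_forward(layers, xva, training = FALSE)$out
    acc <- mean(as.integer(pv[, 2L] >= 0.5) == va$y)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_accuracy = acc))
    if (acc > best_acc) {
      best_acc <- acc
      best_params <- net_params(layers)
      best_epoch <- epoch
    }
  }

  model$layers <- net_set_params(model$layers, best_params)
  structure(list(model = model, history = hist,
                 best_val_accuracy = if (is.finite(best_acc)) best_acc
                                     else NA_real_,
                 best_epoch = best_epoch),
            class = "apnea_train")
}

#' Balance classes by oversampling the minority
#'
#' Duplicates minority-class windows (sampled with replacement, seeded)
#' until both classes have equal counts, then shuffles the order.
#'
#' @param windows List of [segment_window()] (both classes must be
#'   present).
#' @param seed RNG seed.
#' @return A list of windows with equal class counts.
#' @export
oversample_minority <- function(windows, seed = 1L) {
  y <- vapply(windows, `[[`, integer(1), "label")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n0 == 0L || n1 == 0L)
    stop("both classes must be present to oversample", call. = FALSE)
  set.seed(seed)
  minority <- if (n1 < n0) 1L else 0L
  deficit <- abs(n0 - n1)
  if (deficit > 0L) {
    pool <- which(y == minority)
    extra <- pool[sample.int(length(pool), deficit, replace = TRUE)]
    windows <- c(windows, windows[extra])
  }
  windows[sample.int(length(windows))]
}

#' Split windows into train / validation / test sets
#'
#' Seeded random split. At segment granularity the split is stratified
#' by label (each class divided in the given proportions); at recording
#' granularity whole recordings are assigned to one part, which avoids
#' leakage between overlapping context windows of the same record.
#'
#' @param windows List of [segment_window()].
#' @param fractions Length-3 nonnegative proportions for
#'   train/validation/test, summing to 1 (default c(0.8, 0.1, 0.1)).
#' @param by `"segment"` (stratified) or `"recording"`.
#' @param seed RNG seed.
#' @return A list with elements `train`, `val`, `test`.
#' @export
split_windows <- function(windows, fractions = c(0.8, 0.1, 0.1),
                          by = c("segment", "recording"), seed = 1L) {
  by <- match.arg(by)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must be three nonnegative numbers summing to 1",
         call. = FALSE)
  set.seed(seed)
  assign_parts <- function(n) {
    n_tr <- round(fractions[1L] * n)
    n_va <- round(fractions[2L] * n)
    parts <- rep(3L, n)
    ord <- sample.int(n)
    parts[ord[seq_len(n_tr)]] <- 1L
    if (n_va > 0L) parts[ord[n_tr + seq_len(min(n_va, n - n_tr))]] <- 2L
    parts
  }
  part <- integer(length(windows))
  if (by == "segment") {
    y <- vapply(windows, `[[`, integer(1), "label")
    for (cls in unique(y)) {
      ii <- which(y == cls)
      part[ii] <- assign_parts(length(ii))
    }
  } else {
    ids <- vapply(windows, `[[`, character(1), "record_id")
    uids <- unique(ids)
    rec_part <- assign_parts(length(uids))
    part <- rec_part[match(ids, uids)]
  }
  list(train = windows[part == 1L], val = windows[part == 2L],
       test = windows[part == 3L])
}

#' Continue training from pretrained weights
#'
#' Identical to [train()] but starting from the weights of a previously
#' trained (or built) model, for adapting a model to a second cohort.
#' With `epochs = 0` the weights are returned unchanged.
#'
#' @param model An `apnea_model` carrying the pretrained weights.
#' @param train_windows,val_windows Window sets for the new cohort.
#' @param control A [train_control()].
#' @return An `apnea_train` object (see [train()]).
#' @export
finetune <- function(model, train_windows, val_windows,
                     control = train_control()) {
  stopifnot(inherits(model, "apnea_model"))
  tr <- as_batch(train_windows)
  if (dim(tr$x)[2L] != model$input_shape[["s"]] ||
      dim(tr$x)[3L] != model$input_shape[["c"]])
    stop(sprintf(
      "checkpoint incompatible: model input (%d, %d), data (%d, %d)",
      model$input_shape[["s"]], model$input_shape[["c"]],
      dim(tr$x)[2L], dim(tr$x)[3L]), call. = FALSE)
  train(model, tr, val_windows, control)
}
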