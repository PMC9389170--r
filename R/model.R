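# Architecture specification and builder for the stacked
# spatio-temporal network: a stem convolution, then repeated blocks of
# [conv -> max-pool -> dropout -> BiGRU (-> dropout)], dot-product
# attention over the last BiGRU's forward/backward stacks, and a dense
# classification head ending in a 2-way softmax.

#' Network architecture specification
#'
#' Describes the layer stack: a stem convolution, `n_blocks` repeated
#' spatio-temporal blocks (1-D convolution, max-pooling, dropout,
#' bidirectional GRU, and — between blocks — a dropout on the
#' concatenated forward/backward stacks), dot-product attention over the
#' final BiGRU's forward and backward sequences, then
#' flatten -> dense(ReLU) -> dropout -> dense(ReLU) -> dense(2, softmax).
#'
#' @param n_blocks Number of spatio-temporal blocks (default 3, the
#'   configuration that maximises F1 in block-count tuning).
#' @param filters Convolution filters per layer (default 128).
#' @param kernel Convolution kernel size (default 3); convolutions use
#'   "same" zero padding.
#' @param units Hidden units per GRU direction (default 128).
#' @param pool Max-pooling window = stride (default 3; the trailing
#'   remainder is dropped).
#' @param dense_units Sizes of the two hidden dense layers (default
#'   c(64, 64)).
#' @param dropout_rate Dropout probability for every dropout layer
#'   (default 0.2).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(n_blocks = 3L, filters = 128L, kernel = 3L,
                       units = 128L, pool = 3L, dense_units = c(64L, 64L),
                       dropout_rate = 0.2) {
  if (n_blocks < 1L) stop("`n_blocks` must be >= 1", call. = FALSE)
  if (filters < 1L || kernel < 1L || units < 1L || pool < 1L)
    stop("`filters`, `kernel`, `units` and `pool` must be >= 1",
         call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in [0, 1)", call. = FALSE)
  structure(list(n_blocks = as.integer(n_blocks),
                 filters = as.integer(filters),
                 kernel = as.integer(kernel),
                 units = as.integer(units),
                 pool = as.integer(pool),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate),
            class = "model_spec")
}

glorot_mat <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_conv <- function(L, cin, f) {
  lim <- sqrt(6 / (L * cin + L * f))
  list(type = "conv",
       W = array(stats::runif(L * cin * f, -lim, lim), c(L, cin, f)),
       b = numeric(f))
}

init_gru_dir <- function(cin, n) {
  list(Wr = glorot_mat(n, cin), Ur = glorot_mat(n, n),
       Wz = glorot_mat(n, cin), Uz = glorot_mat(n, n),
       Wx = glorot_mat(n, cin), Ux = glorot_mat(n, n),
       br = numeric(n), bz = numeric(n), bc = numeric(n))
}

init_dense <- function(n_in, n_out, activation) {
  list(type = "dense", W = glorot_mat(n_out, n_in), b = numeric(n_out),
       activation = activation)
}

#' Build the trainable network
#'
#' Assembles the layer stack described by a [model_spec()] for a given
#' input shape, initialising weights with Glorot-uniform draws from R's
#' RNG (biases zero). The builder tracks the sequence length through the
#' pooling layers and aborts if it would collapse below one step, naming
#' the offending block; with the default 900-point input, pooling by 3
#' gives block sequence lengths 300, 100 and 33.
#'
#' @param spec A [model_spec()].
#' @param input_shape Length-2 integer vector: (time steps, channels);
#'   default c(900, 2) for the RR + amplitude windows.
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   before weight initialisation.
#' @return An object of class `apnea_model` with elements `layers`,
#'   `spec`, `input_shape`, `seq_lengths` (per-block post-pooling
#'   lengths), `param_count` and `normalization` (NULL until set by a
#'   fitting routine).
#' @export
build_model <- function(spec = model_spec(), input_shape = c(900L, 2L),
                        seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  s <- as.integer(input_shape[1L])
  cin <- as.integer(input_shape[2L])
  k <- spec$kernel
  layers <- list()
  add <- function(ly) layers[[length(layers) + 1L]] <<- ly

  add(init_conv(k, cin, spec$filters))          # stem convolution
  ch <- spec$filters
  seq_lengths <- integer(spec$n_blocks)
  for (blk in seq_len(spec$n_blocks)) {
    add(init_conv(k, ch, spec$filters))
    s_new <- s %/% spec$pool
    if (s_new < 1L)
      stop(sprintf(
        "block %d: sequence length %d collapses below 1 after pooling",
        blk, s), call. = FALSE)
    s <- s_new
    seq_lengths[blk] <- s
    add(list(type = "maxpool", k = spec$pool))
    add(list(type = "dropout", rate = spec$dropout_rate))
    last <- blk == spec$n_blocks
    add(list(type = "bigru",
             fwd = init_gru_dir(spec$filters, spec$units),
             bwd = init_gru_dir(spec$filters, spec$units),
             output = if (last) "pair" else "concat"))
    if (!last) {
      add(list(type = "dropout", rate = spec$dropout_rate))
      ch <- 2L * spec$units
    }
  }
  add(list(type = "attention"))
  add(list(type = "flatten"))
  n_in <- s * spec$units
  add(init_dense(n_in, spec$dense_units[1L], "relu"))
  add(list(type = "dropout", rate = spec$dropout_rate))
  add(init_dense(spec$dense_units[1L], spec$dense_units[2L], "relu"))
  add(init_dense(spec$dense_units[2L], 2L, "softmax"))

  model <- structure(
    list(layers = layers, spec = spec,
         input_shape = c(s = as.integer(input_shape[1L]), c = cin),
         seq_lengths = seq_lengths,
         param_count = tree_count(net_params(layers)),
         normalization = NULL),
    class = "apnea_model")
  model
}

#' Layer table of a built model
#'
#' @param model An `apnea_model`.
#' @return A data.frame with one row per layer: type, output channels /
#'   units, kernel size and activation.
#' @export
model_layer_table <- function(model) {
  stopifnot(inherits(model, "apnea_model"))
  rows <- lapply(model$layers, function(ly) {
    switch(ly$type,
      conv = data.frame(type = "Convolutional",
                        size = dim(ly$W)[3L], kernel = dim(ly$W)[1L],
                        activation = "ReLU"),
      maxpool = data.frame(type = "Max-Pooling", size = NA,
                           kernel = ly$k, activation = NA),
      dropout = data.frame(type = "Dropout", size = NA, kernel = NA,
                           activation = NA),
      bigru = data.frame(type = "Bidirectional GRU",
                         size = nrow(ly$fwd$Wr), kernel = NA,
                         activation = "Tanh"),
      attention = data.frame(type = "Attention", size = NA, kernel = NA,
                             activation = NA),
      flatten = data.frame(type = "Flatten", size = NA, kernel = NA,
                           activation = NA),
      dense = data.frame(type = "Dense", size = nrow(ly$W), kernel = NA,
                         activation = switch(ly$activation,
                                             relu = "ReLU",
                                             softmax = "Softmax",
                                             "Linear")))
  })
  out <- do.call(rbind, rows)
  out$layer <- seq_len(nrow(out))
  out[, c("layer", "type", "size", "kernel", "activation")]
}

#' @export
print.apnea_model <- function(x, ...) {
  cat(sprintf("Spatio-temporal apnea classifier: %d blocks, %s parameters\n",
              x$spec$n_blocks, format(x$param_count, big.mark = ",")))
  cat(sprintf("Input %d x %d; block sequence lengths: %s\n",
              x$input_shape[["s"]], x$input_shape[["c"]],
              paste(x$seq_lengths, collapse = " -> ")))
  print(model_layer_table(x), row.names = FALSE)
  invisible(x)
}

#' Forward pass of a built model
#'
#' Runs the network in inference mode (dropout disabled) and returns the
#' class probabilities; deterministic for fixed weights. The model's
#' stored channel normalization, if any, is applied first.
#'
#' @param model An `apnea_model`.
#' @param x A batch: a (batch, time, 2) array, a single
#'   [segment_window()], or a list of them.
#' @return A (batch x 2) matrix of probabilities with columns `normal`
#'   and `sa`; rows sum to one.
#' @export
model_forward <- function(model, x) {
  stopifnot(inherits(model, "apnea_model"))
  if (!is.array(x) || length(dim(x)) != 3L)
    x <- windows_to_batch(x)$x
  if (dim(x)[2L] != model$input_shape[["s"]] ||
      dim(x)[3L] != model$input_shape[["c"]])
    stop(sprintf("input shape (%d, %d) does not match model input (%d, %d)",
                 dim(x)[2L], dim(x)[3L], model$input_shape[["s"]],
                 model$input_shape[["c"]]), call. = FALSE)
  x <- apply_normalization(x, model$normalization)
  p <- net_forward(model$layers, x, training = FALSE)$out
  colnames(p) <- c("normal", "sa")
  p
}
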