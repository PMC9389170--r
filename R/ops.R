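# Reference implementations of the network's building blocks, written to
# follow the defining equations literally (loops and explicit sums, no
# batching). The trainable engine in network.R is validated against these
# in the test suite; these functions are also usable on their own.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

#' One-dimensional convolution (reference)
#'
#' Cross-correlation of a (possibly multi-channel) series with a filter
#' bank, summed over input channels:
#' `out[i, f] = sum_u sum_c w[u, c, f] * x[i + u - 1, c]`.
#' No activation is applied; layer wrappers add ReLU.
#'
#' @param x Numeric vector (single channel) or `s x c` matrix.
#' @param w Numeric vector (single filter on a single channel) or
#'   `L x c x f` array.
#' @param padding `"valid"` (no padding) or `"same"` (zero-pad so the
#'   output length equals the input length).
#' @return An `s' x f` matrix of filter responses (dropped to a vector
#'   when both `x` and `w` are vectors).
#' @export
conv1d <- function(x, w, padding = c("valid", "same")) {
  padding <- match.arg(padding)
  vec_in <- is.null(dim(x)) && is.null(dim(w))
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (is.null(dim(w))) w <- array(w, dim = c(length(w), 1L, 1L))
  L <- dim(w)[1L]; cw <- dim(w)[2L]; f <- dim(w)[3L]
  if (ncol(x) != cw)
    stop(sprintf("filter expects %d channel(s), input has %d", cw,
                 ncol(x)), call. = FALSE)
  if (padding == "same") {
    pad_l <- (L - 1L) %/% 2L
    pad_r <- L - 1L - pad_l
    x <- rbind(matrix(0, pad_l, ncol(x)), x, matrix(0, pad_r, ncol(x)))
  }
  s_out <- nrow(x) - L + 1L
  if (s_out < 1L)
    stop("kernel longer than (padded) input", call. = FALSE)
  out <- matrix(0, s_out, f)
  for (k in seq_len(f))
    for (i in seq_len(s_out))
      for (u in seq_len(L))
        out[i, k] <- out[i, k] + sum(w[u, , k] * x[i + u - 1L, ])
  if (vec_in) drop(out) else out
}

#' Non-overlapping max pooling (reference)
#'
#' Maximum over consecutive windows of length `k` with stride `k`; a
#' trailing remainder shorter than `k` is dropped.
#'
#' @param x Numeric vector or `s x c` matrix (pooled per column).
#' @param k Window length (>= 1; default 3).
#' @return Pooled vector or matrix with `floor(s / k)` rows.
#' @export
max_pool <- function(x, k = 3L) {
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, ncol = 1L)
  s_out <- nrow(x) %/% k
  if (s_out < 1L) stop("input shorter than pooling window", call. = FALSE)
  out <- matrix(0, s_out, ncol(x))
  for (j in seq_len(s_out))
    out[j, ] <- apply(x[((j - 1L) * k + 1L):(j * k), , drop = FALSE],
                      2L, max)
  if (vec_in) drop(out) else out
}

#' GRU cell parameters
#'
#' Bias-free gated-recurrent-unit parameters: the six weight matrices of
#' the reset gate, update gate and candidate state.
#'
#' @param W_r,W_z,W_x `n x c` input weight matrices.
#' @param U_r,U_z,U_x `n x n` recurrent weight matrices.
#' @return An object of class `gru_params`.
#' @export
gru_params <- function(W_r, U_r, W_z, U_z, W_x, U_x) {
  p <- list(W_r = as.matrix(W_r), U_r = as.matrix(U_r),
            W_z = as.matrix(W_z), U_z = as.matrix(U_z),
            W_x = as.matrix(W_x), U_x = as.matrix(U_x))
  n <- nrow(p$W_r)
  c_in <- ncol(p$W_r)
  for (nm in c("W_z", "W_x"))
    if (!all(dim(p[[nm]]) == c(n, c_in)))
      stop(sprintf("%s must be %d x %d", nm, n, c_in), call. = FALSE)
  for (nm in c("U_r", "U_z", "U_x"))
    if (!all(dim(p[[nm]]) == c(n, n)))
      stop(sprintf("%s must be %d x %d", nm, n, n), call. = FALSE)
  structure(c(p, list(n = n, c_in = c_in)), class = "gru_params")
}

#' One GRU step (reference)
#'
#' Literal gate equations: reset `r = sigma(W_r x + U_r h)`, update
#' `z = sigma(W_z x + U_z h)`, candidate
#' `h~ = tanh(W_x x + r * (U_x h))`, and new state
#' `h' = z * h + (1 - z) * h~` (the update gate multiplies the previous
#' state).
#'
#' @param p A [gru_params()] object.
#' @param h_prev Previous hidden state, length `n`.
#' @param x_t Input vector, length `c_in`.
#' @return New hidden state, length `n`.
#' @export
gru_step <- function(p, h_prev, x_t) {
  stopifnot(inherits(p, "gru_params"))
  h_prev <- as.numeric(h_prev); x_t <- as.numeric(x_t)
  if (length(h_prev) != p$n)
    stop(sprintf("`h_prev` must have length %d", p$n), call. = FALSE)
  if (length(x_t) != p$c_in)
    stop(sprintf("`x_t` must have length %d", p$c_in), call. = FALSE)
  r <- sigmoid(drop(p$W_r %*% x_t) + drop(p$U_r %*% h_prev))
  z <- sigmoid(drop(p$W_z %*% x_t) + drop(p$U_z %*% h_prev))
  h_tilde <- tanh(drop(p$W_x %*% x_t) + r * drop(p$U_x %*% h_prev))
  z * h_prev + (1 - z) * h_tilde
}

#' Bidirectional GRU run (reference)
#'
#' Runs a forward GRU over the sequence and a backward GRU over the
#' reversed sequence, both from zero initial states. The backward stack is
#' re-reversed so that row `t` of both outputs is aligned with input step
#' `t`: `F[t, ]` is the forward state after consuming steps `1..t`, and
#' `B[t, ]` the backward state after consuming steps `s..t`.
#'
#' @param p_fwd,p_bwd [gru_params()] for the two directions.
#' @param seq_x `s x c` input matrix (one row per time step).
#' @return A list with `s x n` matrices `F` and `B`.
#' @export
bigru_run <- function(p_fwd, p_bwd, seq_x) {
  seq_x <- as.matrix(seq_x)
  s <- nrow(seq_x)
  if (s < 1L) stop("empty sequence", call. = FALSE)
  n <- p_fwd$n
  F_out <- matrix(0, s, n)
  h <- numeric(n)
  for (t in seq_len(s)) {
    h <- gru_step(p_fwd, h, seq_x[t, ])
    F_out[t, ] <- h
  }
  B_out <- matrix(0, s, p_bwd$n)
  h <- numeric(p_bwd$n)
  for (t in seq.int(s, 1L)) {
    h <- gru_step(p_bwd, h, seq_x[t, ])
    B_out[t, ] <- h
  }
  list(F = F_out, B = B_out)
}

#' Dot-product attention (reference)
#'
#' `a = softmax(F B^T) B`, with the softmax taken row-wise over the `s`
#' key positions: each output row is a similarity-weighted mixture of the
#' backward states.
#'
#' @param F_mat,B_mat `s x n` matrices (forward and backward stacks).
#' @return An `s x n` attention output.
#' @export
dot_attention <- function(F_mat, B_mat) {
  F_mat <- as.matrix(F_mat); B_mat <- as.matrix(B_mat)
  if (!all(dim(F_mat) == dim(B_mat)))
    stop("`F` and `B` must have identical shape", call. = FALSE)
  softmax_rows(F_mat %*% t(B_mat)) %*% B_mat
}
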