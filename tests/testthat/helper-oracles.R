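# Brute-force oracles and small fixture builders, independent of the
# package's implementations: plain loops and closed forms only.

# valid-mode convolution by explicit double loop
bf_conv_valid <- function(x, w) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.null(dim(w))) w <- array(w, c(length(w), 1, 1))
  L <- dim(w)[1]; f <- dim(w)[3]
  s_out <- nrow(x) - L + 1
  out <- matrix(0, s_out, f)
  for (k in seq_len(f))
    for (i in seq_len(s_out)) {
      acc <- 0
      for (u in seq_len(L))
        for (ch in seq_len(ncol(x)))
          acc <- acc + w[u, ch, k] * x[i + u - 1, ch]
      out[i, k] <- acc
    }
  out
}

bf_maxpool <- function(x, k) {
  s_out <- length(x) %/% k
  vapply(seq_len(s_out),
         function(j) max(x[((j - 1) * k + 1):(j * k)]), numeric(1))
}

# scalar, element-by-element GRU step following the gate equations
bf_gru_step <- function(p, h_prev, x_t) {
  n <- nrow(p$W_r)
  h_new <- numeric(n)
  for (j in seq_len(n)) {
    r_j <- 1 / (1 + exp(-(sum(p$W_r[j, ] * x_t) +
                            sum(p$U_r[j, ] * h_prev))))
    z_j <- 1 / (1 + exp(-(sum(p$W_z[j, ] * x_t) +
                            sum(p$U_z[j, ] * h_prev))))
    hud <- sum(p$U_x[j, ] * h_prev)
    htilde <- tanh(sum(p$W_x[j, ] * x_t) + r_j * hud)
    h_new[j] <- z_j * h_prev[j] + (1 - z_j) * htilde
  }
  h_new
}

# per-row softmax then weighted sum, all explicit
bf_attention <- function(Fm, Bm) {
  s <- nrow(Fm); n <- ncol(Fm)
  out <- matrix(0, s, n)
  for (i in seq_len(s)) {
    sim <- numeric(s)
    for (j in seq_len(s)) sim[j] <- sum(Fm[i, ] * Bm[j, ])
    e <- exp(sim - max(sim))
    a <- e / sum(e)
    for (j in seq_len(s)) out[i, ] <- out[i, ] + a[j] * Bm[j, ]
  }
  out
}

# AUC by explicit pair counting, ties as 1/2
bf_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# AUC by trapezoidal integration of the empirical ROC curve
bf_auc_trapezoid <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0); fpr <- c(0)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  for (t in thr) {
    tpr <- c(tpr, sum(scores >= t & labels == 1) / npos)
    fpr <- c(fpr, sum(scores >= t & labels == 0) / nneg)
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# per-second occupancy counter for integer-second events
bf_minute_labels <- function(onsets, durations, n_minutes,
                             threshold_s = 5) {
  total <- n_minutes * 60
  occupied <- logical(total)     # second k covers [k-1, k)
  for (i in seq_along(onsets)) {
    secs <- seq.int(onsets[i] + 1, min(onsets[i] + durations[i], total))
    occupied[secs] <- TRUE
  }
  vapply(seq_len(n_minutes), function(m) {
    as.integer(sum(occupied[((m - 1) * 60 + 1):(m * 60)]) > threshold_s)
  }, integer(1))
}

# toy linearly separable windows: two classes differ by a mean shift in
# both channels; short windows keep the unit tests fast
toy_windows <- function(n = 40, len = 60, shift = 1.5, seed = 1,
                        record_ids = NULL) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  if (is.null(record_ids)) record_ids <- rep("toy", n)
  lapply(seq_len(n), function(i) {
    mu <- shift * y[i]
    segment_window(record_ids[i], i - 1L,
                   rnorm(len, mean = mu, sd = 0.5),
                   rnorm(len, mean = -mu, sd = 0.5),
                   y[i])
  })
}

# random beat series with sparse, isolated RR outliers
random_beat_series <- function(n_beats = 80, outlier_frac = 0.05,
                               seed = 1) {
  set.seed(seed)
  rr <- rnorm(n_beats - 1, 0.85, 0.03)
  n_out <- max(1, round(outlier_frac * length(rr)))
  pos <- seq(5, length(rr) - 5, length.out = n_out)
  pos <- unique(round(pos))
  rr[pos] <- sample(c(3.0, 0.2, 1.6), length(pos), replace = TRUE)
  times <- cumsum(c(1, rr))
  beat_series(times, rnorm(n_beats, 1, 0.05), "rand")
}

tiny_sim_cfg <- function(duration_s = 120, apnea_intervals = list(),
                         noise_sd = 0, seed = 3, ...) {
  sim_config(record_id = "tst", duration_s = duration_s,
             apnea_intervals = apnea_intervals, noise_sd = noise_sd,
             seed = seed, ...)
}
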