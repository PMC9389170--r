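# Beat-level preprocessing: Hamilton-style R-peak detection, RR/amplitude
# extraction, artifact cleaning, and resampling of 5-minute context
# windows into fixed-length model inputs.

#' Detect R-peaks in a single-lead ECG
#'
#' Hamilton-family QRS detector: the signal is band-pass filtered
#' (zero-phase Butterworth), rectified and smoothed with a short moving
#' average to form a detection envelope; envelope maxima are accepted
#' against an adaptive threshold that tracks a running average of accepted
#' peak heights, with a refractory period; each accepted detection is then
#' refined to the local maximum of the raw signal within a small
#' neighbourhood so the reported sample sits on the R-peak itself.
#'
#' @param ecg An [ecg_record()]. At least one second of signal is assumed.
#' @param bandpass Band-pass corner frequencies in Hz (default c(8, 16),
#'   the QRS energy band).
#' @param integrate_s Moving-average width in seconds for the envelope
#'   (default 0.08).
#' @param threshold_frac Detection threshold as a fraction of the running
#'   average of accepted envelope peak heights (default 0.3125).
#' @param refractory_s Minimum spacing between accepted peaks in seconds
#'   (default 0.2).
#' @param refine_s Half-width in seconds of the local-maximum refinement
#'   window on the raw signal (default 0.05).
#' @param min_env Absolute envelope noise floor in mV (default 0.02);
#'   candidates below it are never beats, which keeps numerical ripple
#'   in silent stretches from seeding the adaptive threshold.
#' @return Integer vector of ascending R-peak sample indices (1-based);
#'   may be empty (e.g. on a flat signal).
#' @export
detect_r_peaks <- function(ecg, bandpass = c(8, 16), integrate_s = 0.08,
                           threshold_frac = 0.3125, refractory_s = 0.2,
                           refine_s = 0.05, min_env = 0.02) {
  stopifnot(inherits(ecg, "ecg_record"))
  x <- ecg$signal
  fs <- ecg$fs
  n <- length(x)
  if (n < max(30L, as.integer(fs))) return(integer(0))

  bf <- signal::butter(2, pmin(bandpass / (fs / 2), 0.99), type = "pass")
  filt <- signal::filtfilt(bf, x)
  env <- abs(filt)
  w <- max(1L, as.integer(round(integrate_s * fs)))
  env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0

  # candidate envelope maxima
  cand <- which(env[2:(n - 1L)] > env[1:(n - 2L)] &
                  env[2:(n - 1L)] >= env[3:n]) + 1L
  if (!length(cand)) return(integer(0))

  refractory <- refractory_s * fs
  cand <- cand[env[cand] > min_env]
  if (!length(cand)) return(integer(0))

  init_span <- seq_len(min(n, as.integer(2 * fs)))
  peak_avg <- max(env[init_span])
  if (peak_avg <= min_env) peak_avg <- max(env)  # no beat in learning span

  accepted <- integer(0)
  last <- -Inf
  for (c_i in cand) {
    if (c_i - last < refractory) next
    if (env[c_i] > threshold_frac * peak_avg) {
      accepted <- c(accepted, c_i)
      last <- c_i
      peak_avg <- 0.875 * peak_avg + 0.125 * env[c_i]
    }
  }
  if (!length(accepted)) return(integer(0))

  # refine to local raw-signal maximum
  half <- as.integer(round(refine_s * fs))
  refined <- vapply(accepted, function(p) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # refinement can pull neighbours together; re-enforce the refractory gap
  if (length(refined) > 1L) {
    keep <- c(TRUE, diff(refined) >= refractory)
    while (!all(keep)) {
      refined <- refined[keep]
      if (length(refined) < 2L) break
      keep <- c(TRUE, diff(refined) >= refractory)
    }
  }
  as.integer(refined)
}

#' Beat series from detected peaks
#'
#' Converts peak sample indices into beat times, successive RR intervals
#' and R-peak amplitudes (the signal value at each peak).
#'
#' @param ecg An [ecg_record()].
#' @param peaks Ascending 1-based peak sample indices within the signal.
#' @return A [beat_series()].
#' @export
extract_beat_series <- function(ecg, peaks) {
  stopifnot(inherits(ecg, "ecg_record"))
  peaks <- as.integer(peaks)
  if (length(peaks)) {
    if (any(peaks < 1L | peaks > length(ecg$signal)))
      stop("peak indices out of signal bounds", call. = FALSE)
    if (length(peaks) > 1L && any(diff(peaks) <= 0))
      stop("peak indices must be strictly ascending", call. = FALSE)
  }
  beat_series(times = (peaks - 1L) / ecg$fs + ecg$start_time,
              amp = ecg$signal[peaks],
              record_id = ecg$record_id)
}

#' Clean RR intervals and amplitudes
#'
#' Replaces physiologically unexplained RR intervals — values outside
#' `[lo_s, hi_s]` or deviating from a running median by more than
#' `dev_frac` (fractionally) — with that running median; the amplitudes at
#' the affected beats are replaced by the amplitudes' own running median.
#' All other points are returned unchanged.
#'
#' @param series A [beat_series()].
#' @param lo_s,hi_s Plausible RR range in seconds (defaults 0.4 and 2.0,
#'   i.e. 30-150 bpm).
#' @param dev_frac Maximum tolerated fractional deviation from the running
#'   median (default 0.2).
#' @param median_k Running-median window length, odd, >= 3 (default 5).
#' @param clean_amp Whether to median-replace amplitudes at flagged beats
#'   (default TRUE).
#' @return A cleaned [beat_series()] with the same beat times.
#' @export
clean_rr <- function(series, lo_s = 0.4, hi_s = 2.0, dev_frac = 0.2,
                     median_k = 5L, clean_amp = TRUE) {
  stopifnot(inherits(series, "beat_series"))
  if (lo_s >= hi_s) stop("`lo_s` must be < `hi_s`", call. = FALSE)
  if (median_k < 3L || median_k %% 2L == 0L)
    stop("`median_k` must be odd and >= 3", call. = FALSE)
  rr <- series$rr
  if (!length(rr)) return(series)

  k <- min(median_k, if (length(rr) %% 2L == 1L) length(rr)
           else length(rr) - 1L)
  med <- if (k >= 3L)
    as.numeric(stats::runmed(rr, k, endrule = "median")) else rr
  bad <- rr < lo_s | rr > hi_s | abs(rr - med) > dev_frac * med
  rr[bad] <- med[bad]

  amp <- series$amp
  if (clean_amp && any(bad)) {
    ka <- min(median_k, if (length(amp) %% 2L == 1L) length(amp)
              else length(amp) - 1L)
    amed <- if (ka >= 3L)
      as.numeric(stats::runmed(amp, ka, endrule = "median")) else amp
    # rr[i] is attributed to beat i + 1
    amp[which(bad) + 1L] <- amed[which(bad) + 1L]
  }
  out <- beat_series(series$times, amp, series$record_id)
  out$rr <- rr
  out
}

#' Resample a beat-time window to fixed-length channels
#'
#' Cubic-spline interpolation of the RR and amplitude series, as functions
#' of beat time, onto `n` uniformly spaced points spanning `[t0, t1]`.
#' Evaluation points outside the knot range are clamped to the nearest
#' knot value. Because an RR interval is attributed to the later beat, the
#' knots are the beats inside the window that carry an RR value.
#'
#' @param series A [beat_series()].
#' @param t0,t1 Window bounds in seconds (t1 > t0; 300 s windows in the
#'   standard pipeline).
#' @param n Number of output points per channel (default 900).
#' @return A list with numeric `rr_channel` and `amp_channel`, each of
#'   length `n`. Signals a condition of class `apnea_sparse_beats` when
#'   fewer than four usable beats fall inside the window (cubic
#'   interpolation needs four knots); callers drop such windows.
#' @export
resample_window <- function(series, t0, t1, n = 900L) {
  stopifnot(inherits(series, "beat_series"))
  if (t1 <= t0) stop("`t1` must be > `t0`", call. = FALSE)
  # beats with an RR attribution (index >= 2) inside [t0, t1]
  idx <- which(series$times >= t0 & series$times <= t1)
  idx <- idx[idx >= 2L]
  if (length(idx) < 4L)
    stop(structure(
      class = c("apnea_sparse_beats", "error", "condition"),
      list(message = sprintf(
        "window [%g, %g) has %d usable beats; >= 4 required",
        t0, t1, length(idx)), call = NULL)))
  kt <- series$times[idx]
  grid <- seq(t0, t1, length.out = n)
  gx <- pmin(pmax(grid, kt[1L]), kt[length(kt)])
  rr_channel <- stats::spline(kt, series$rr[idx - 1L], xout = gx,
                              method = "natural")$y
  amp_channel <- stats::spline(kt, series$amp[idx], xout = gx,
                               method = "natural")$y
  list(rr_channel = rr_channel, amp_channel = amp_channel)
}

#' Build labeled model-input windows for a record
#'
#' For every labeled minute `m` with full two-minute context on both sides
#' (0-based `2 <= m <= M - 3` for `M` labeled minutes), extracts the
#' five-minute span `[60(m-2), 60(m+3))`, resamples it with
#' [resample_window()], and attaches the centre minute's label. Minutes
#' lacking full context, or whose window has too few beats, are dropped.
#'
#' @param series A [beat_series()] (typically cleaned with [clean_rr()]).
#' @param labels A [minute_labels()] covering the record.
#' @param n Points per channel (default 900).
#' @param context_min Context minutes on each side (default 2).
#' @return A list of [segment_window()] objects (possibly empty).
#' @export
build_windows <- function(series, labels, n = 900L, context_min = 2L) {
  stopifnot(inherits(series, "beat_series"),
            inherits(labels, "minute_labels"))
  M <- length(labels$labels)
  span <- 2L * context_min + 1L
  if (M < span) return(list())
  centers <- seq.int(context_min, M - context_min - 1L)
  out <- vector("list", length(centers))
  keep <- logical(length(centers))
  for (j in seq_along(centers)) {
    m <- centers[j]
    t0 <- 60 * (m - context_min)
    t1 <- 60 * (m + context_min + 1L)
    ch <- tryCatch(resample_window(series, t0, t1, n = n),
                   apnea_sparse_beats = function(e) NULL)
    if (is.null(ch)) next
    out[[j]] <- segment_window(series$record_id, m, ch$rr_channel,
                               ch$amp_channel, labels$labels[m + 1L])
    keep[j] <- TRUE
  }
  out[keep]
}

#' Full preprocessing of one record
#'
#' Convenience wrapper: detect R-peaks, extract and clean the beat series,
#' and build labeled windows.
#'
#' @param ecg An [ecg_record()].
#' @param labels A [minute_labels()] for the record.
#' @param ... Passed on to [clean_rr()].
#' @return A list of [segment_window()] objects.
#' @export
preprocess_record <- function(ecg, labels, ...) {
  peaks <- detect_r_peaks(ecg)
  series <- clean_rr(extract_beat_series(ecg, peaks), ...)
  build_windows(series, labels)
}

# Stack a list of segment_window into arrays for the network:
# x is (batch, n, 2) with channel 1 = RR, channel 2 = amplitude.
windows_to_batch <- function(windows) {
  if (!length(windows)) stop("empty window set", call. = FALSE)
  if (inherits(windows, "segment_window")) windows <- list(windows)
  n <- length(windows[[1L]]$rr_channel)
  b <- length(windows)
  x <- array(0, dim = c(b, n, 2L))
  y <- integer(b)
  for (i in seq_len(b)) {
    w <- windows[[i]]
    x[i, , 1L] <- w$rr_channel
    x[i, , 2L] <- w$amp_channel
    y[i] <- w$label
  }
  list(x = x, y = y,
       record_id = vapply(windows, `[[`, character(1), "record_id"),
       center_minute = vapply(windows, `[[`, integer(1), "center_minute"))
}

# Channel-wise z-score statistics over a training batch.
batch_normalization <- function(x) {
  mu <- c(mean(x[, , 1L]), mean(x[, , 2L]))
  sd_ <- c(stats::sd(as.numeric(x[, , 1L])),
           stats::sd(as.numeric(x[, , 2L])))
  sd_[sd_ < 1e-12] <- 1
  list(mean = mu, sd = sd_)
}

apply_normalization <- function(x, norm) {
  if (is.null(norm)) return(x)
  for (ch in 1:2)
    x[, , ch] <- (x[, , ch] - norm$mean[ch]) / norm$sd[ch]
  x
}
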