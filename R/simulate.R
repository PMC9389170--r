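# Synthetic single-lead ECG with known beats and planted apnea episodes.
# Apnea physiology is modelled only as the cyclic bradycardia-tachycardia
# RR oscillation and R-amplitude modulation that the classifier's two
# input channels can see; morphology beyond a biphasic QRS-like template
# (P/T waves, arrhythmias, electrode artefacts) is deliberately absent.

#' Simulation configuration
#'
#' @param record_id Record identifier (default "sim01").
#' @param fs Sampling rate in Hz (default 100).
#' @param duration_s Record duration in seconds (default 1800).
#' @param base_rr_mean,base_rr_sd Baseline RR interval mean and SD in
#'   seconds (defaults 0.85 and 0.02).
#' @param apnea_intervals List of `c(start_s, end_s)` apnea episodes,
#'   non-overlapping, within `[0, duration_s]`.
#' @param apnea_cycle_s Period of the cyclic RR/amplitude oscillation
#'   during apnea in seconds (default 40).
#' @param apnea_rr_depth Fractional RR swing during apnea (default 0.25).
#' @param apnea_amp_depth Fractional R-amplitude swing during apnea
#'   (default 0.3).
#' @param amp_jitter_sd SD of the beat-to-beat amplitude jitter in mV
#'   (default 0.02).
#' @param noise_sd SD of additive Gaussian signal noise in mV
#'   (default 0.05).
#' @param seed RNG seed (default 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(record_id = "sim01", fs = 100, duration_s = 1800,
                       base_rr_mean = 0.85, base_rr_sd = 0.02,
                       apnea_intervals = list(), apnea_cycle_s = 40,
                       apnea_rr_depth = 0.25, apnea_amp_depth = 0.3,
                       amp_jitter_sd = 0.02, noise_sd = 0.05,
                       seed = 1L) {
  if (fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  rr_hi <- base_rr_mean * (1 + apnea_rr_depth) + 5 * base_rr_sd
  rr_lo <- base_rr_mean * (1 - apnea_rr_depth) - 5 * base_rr_sd
  if (rr_lo <= 0.3 || rr_hi >= 2.5)
    stop("RR parameters leave the physiological band (0.3, 2.5) s",
         call. = FALSE)
  iv <- lapply(apnea_intervals, function(x) as.numeric(x[1:2]))
  if (length(iv)) {
    m <- do.call(rbind, iv)
    if (any(m[, 1L] < 0) || any(m[, 2L] > duration_s) ||
        any(m[, 2L] <= m[, 1L]))
      stop("apnea intervals must satisfy 0 <= start < end <= duration",
           call. = FALSE)
    m <- m[order(m[, 1L]), , drop = FALSE]
    if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L]))
      stop("apnea intervals must not overlap", call. = FALSE)
    iv <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  }
  structure(list(record_id = record_id, fs = fs, duration_s = duration_s,
                 base_rr_mean = base_rr_mean, base_rr_sd = base_rr_sd,
                 apnea_intervals = iv, apnea_cycle_s = apnea_cycle_s,
                 apnea_rr_depth = apnea_rr_depth,
                 apnea_amp_depth = apnea_amp_depth,
                 amp_jitter_sd = amp_jitter_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

in_any_interval <- function(t, intervals) {
  for (iv in intervals) if (t >= iv[1L] && t < iv[2L]) return(TRUE)
  FALSE
}

#' Generate ground-truth beats and labels
#'
#' Sequentially draws beat times: outside apnea episodes each RR interval
#' is Normal(base mean, base SD); inside an episode the RR mean is
#' modulated by `1 + depth * sin(2 * pi * t / cycle)` — the cyclic
#' bradycardia-tachycardia pattern that accompanies apneas — with the
#' same jitter. R-amplitudes sit at 1 mV, modulated by the amplitude
#' depth during apnea, with small beat-to-beat jitter. Per-minute labels
#' follow the >5 s event-occupancy rule applied to the episode list.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `ground_truth` with `beat_times` (s),
#'   `beat_amplitudes` (mV), `minute_labels` (a [minute_labels()]) and
#'   the originating `cfg`.
#' @export
generate_beats <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  times <- numeric(0)
  amps <- numeric(0)
  t <- cfg$base_rr_mean
  while (t < cfg$duration_s - 0.2) {
    apneic <- in_any_interval(t, cfg$apnea_intervals)
    phase <- sin(2 * pi * t / cfg$apnea_cycle_s)
    a <- 1 + (if (apneic) cfg$apnea_amp_depth * phase else 0) +
      stats::rnorm(1L, 0, cfg$amp_jitter_sd)
    times <- c(times, t)
    amps <- c(amps, a)
    mu <- if (apneic)
      cfg$base_rr_mean * (1 + cfg$apnea_rr_depth * phase)
    else cfg$base_rr_mean
    rr <- min(max(mu + stats::rnorm(1L, 0, cfg$base_rr_sd), 0.3), 2.5)
    t <- t + rr
  }
  events <- if (length(cfg$apnea_intervals)) {
    data.frame(
      onset_s = vapply(cfg$apnea_intervals, `[[`, numeric(1), 1L),
      duration_s = vapply(cfg$apnea_intervals,
                          function(x) x[2L] - x[1L], numeric(1)),
      event_type = "APNEA")
  } else {
    data.frame(onset_s = numeric(0), duration_s = numeric(0),
               event_type = character(0))
  }
  labels <- ucddb_minute_labels(events,
                                n_minutes = floor(cfg$duration_s / 60),
                                record_id = cfg$record_id)
  structure(list(beat_times = times, beat_amplitudes = amps,
                 minute_labels = labels, cfg = cfg),
            class = "ground_truth")
}

# biphasic QRS-like template, ~100 ms wide, unit peak exactly at its
# argmax sample
qrs_template <- function(fs) {
  half <- round(0.05 * fs)
  tt <- (-half:half) / fs
  w <- exp(-(tt / 0.012)^2 / 2) - 0.35 * exp(-((tt - 0.03) / 0.015)^2 / 2)
  k0 <- which.max(w)
  list(w = w / w[k0], k0 = k0)
}

#' Render ground-truth beats as an ECG signal
#'
#' Places a fixed biphasic QRS-like template (about 100 ms wide, unit
#' peak) at each beat time, scaled by the beat's amplitude, and adds
#' Gaussian noise. With zero noise the signal's local maximum at each
#' beat is exactly the beat's amplitude at the beat's sample.
#'
#' @param truth A `ground_truth` from [generate_beats()].
#' @param cfg The same [sim_config()] (defaults to `truth$cfg`).
#' @return An [ecg_record()] of `duration_s * fs` samples.
#' @export
synthesize_ecg <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- round(cfg$duration_s * cfg$fs)
  tpl <- qrs_template(cfg$fs)
  if (length(truth$beat_times) > 1L &&
      min(diff(truth$beat_times)) <= length(tpl$w) / cfg$fs)
    stop("QRS template wider than the shortest RR interval",
         call. = FALSE)
  x <- numeric(n)
  for (i in seq_along(truth$beat_times)) {
    s0 <- round(truth$beat_times[i] * cfg$fs) + 1L
    idx <- s0 - tpl$k0 + seq_along(tpl$w)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + truth$beat_amplitudes[i] * tpl$w[ok]
  }
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed + 1L)
    x <- x + stats::rnorm(n, 0, cfg$noise_sd)
  }
  ecg_record(cfg$record_id, cfg$fs, x)
}

# random non-overlapping apnea episodes targeting a given fraction of
# SA-labeled minutes; episode lengths ~ U(120, 300) s. An episode of
# length ep straddling minute boundaries labels about (ep + 50)/60
# minutes under the >5 s rule (each boundary minute flips once >5 s is
# covered), so gaps are scaled to make that ratio hit the target.
random_apnea_intervals <- function(duration_s, prevalence,
                                   ep_range = c(120, 300)) {
  ep_mean <- mean(ep_range)
  gap_mean <- (ep_mean + 50) / prevalence - ep_mean
  iv <- list()
  t <- stats::runif(1L, 0.3, 1.2) * gap_mean / 2
  while (t < duration_s) {
    ep <- stats::runif(1L, ep_range[1L], ep_range[2L])
    if (t + 10 > duration_s) break
    iv[[length(iv) + 1L]] <- c(t, min(t + ep, duration_s))
    t <- t + ep + stats::runif(1L, 0.6, 1.4) * gap_mean
  }
  iv
}

#' Generate a synthetic cohort on disk
#'
#' Writes `n_records` synthetic recordings as WFDB format-16 records with
#' plain-text per-minute annotations, plus a JSON manifest carrying the
#' full ground truth (beat times, amplitudes, labels, apnea episodes,
#' per-record seeds). Per-record seeds are derived deterministically from
#' the master seed, so each record is independently reproducible and the
#' manifest is byte-identical across runs with the same seed.
#'
#' @param n_records Number of records (>= 1).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param duration_s Per-record duration in seconds (default 1800).
#' @param prevalence Target fraction of time inside apnea episodes
#'   (default 0.3).
#' @param ... Further arguments passed to [sim_config()] (e.g.
#'   `noise_sd`, `fs`).
#' @return Invisibly, the manifest (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
generate_dataset <- function(n_records, out_dir, seed = 1L,
                             duration_s = 1800, prevalence = 0.3, ...) {
  if (n_records < 1L) stop("`n_records` must be >= 1", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  records <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    seed_r <- as.integer(seed + 1000L * r)
    set.seed(seed_r)
    iv <- random_apnea_intervals(duration_s, prevalence)
    cfg <- sim_config(record_id = sprintf("sim%02d", r),
                      duration_s = duration_s, apnea_intervals = iv,
                      seed = seed_r + 500L, ...)
    truth <- generate_beats(cfg)
    ecg <- synthesize_ecg(truth, cfg)
    write_wfdb_record(ecg, out_dir)
    write_apnea_minute_labels(
      truth$minute_labels,
      file.path(out_dir, paste0(cfg$record_id, ".apn.txt")))
    records[[r]] <- list(
      record_id = cfg$record_id, seed = seed_r,
      n_minutes = length(truth$minute_labels$labels),
      labels = truth$minute_labels$labels,
      apnea_intervals = lapply(cfg$apnea_intervals, round, digits = 6),
      beat_times = round(truth$beat_times, 6),
      beat_amplitudes = round(truth$beat_amplitudes, 6))
  }
  manifest <- list(master_seed = as.integer(seed),
                   n_records = as.integer(n_records),
                   duration_s = duration_s, prevalence = prevalence,
                   records = records)
  jsonlite::write_json(manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param out_dir Directory written by [generate_dataset()].
#' @return The manifest list.
#' @export
read_manifest <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "manifest.json"),
                      simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
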