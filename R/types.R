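#' Single-lead ECG record
#'
#' Container for one continuous single-lead ECG trace. Voltages are stored in
#' millivolts; time is implicit from the sampling rate.
#'
#' @param record_id Character identifier.
#' @param fs Sampling rate in Hz (> 0).
#' @param signal Numeric vector of voltage samples (mV), length >= 1.
#' @param start_time Offset of the first sample in seconds (default 0).
#'
#' @return An object of class `ecg_record` with fields `record_id`, `fs`,
#'   `signal` and `start_time`; its duration in seconds is
#'   `length(signal)/fs`.
#' @export
ecg_record <- function(record_id, fs, signal, start_time = 0) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  signal <- as.numeric(signal)
  if (length(signal) < 1L)
    stop("`signal` must contain at least one sample", call. = FALSE)
  structure(
    list(record_id = as.character(record_id), fs = fs, signal = signal,
         start_time = start_time),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s': %d samples @ %g Hz = %.1f s>\n",
              x$record_id, length(x$signal), x$fs,
              length(x$signal) / x$fs))
  invisible(x)
}

#' Duration of an ECG record in seconds
#' @param x An `ecg_record`.
#' @return Duration in seconds.
#' @export
ecg_duration <- function(x) {
  stopifnot(inherits(x, "ecg_record"))
  length(x$signal) / x$fs
}

#' Per-minute apnea labels
#'
#' One binary label per consecutive one-minute segment of a recording:
#' 0 = normal, 1 = sleep apnea. Minute `i` (0-based) covers the half-open
#' interval `[60*i, 60*(i+1))` seconds, and `labels[i + 1]` is its label.
#'
#' @param record_id Character identifier.
#' @param labels Integer vector with values in {0, 1}; may be empty.
#' @return An object of class `minute_labels`.
#' @export
minute_labels <- function(record_id, labels) {
  labels <- as.integer(labels)
  if (length(labels) && !all(labels %in% c(0L, 1L)))
    stop("minute labels must be 0 (normal) or 1 (apnea)", call. = FALSE)
  structure(list(record_id = as.character(record_id), labels = labels),
            class = "minute_labels")
}

#' @export
print.minute_labels <- function(x, ...) {
  cat(sprintf("<minute_labels '%s': %d minutes, %d apneic>\n",
              x$record_id, length(x$labels), sum(x$labels)))
  invisible(x)
}

#' Detected beat series for a record
#'
#' R-peak times, RR intervals and R-peak amplitudes. The RR interval
#' `rr[i]` equals `times[i + 1] - times[i]` and is attributed to the later
#' beat, so `rr` has one element fewer than `times` (and is empty with
#' fewer than two peaks).
#'
#' @param times R-peak times in seconds, strictly increasing.
#' @param amp R-peak amplitudes in mV, aligned with `times`.
#' @param record_id Optional record identifier.
#' @return An object of class `beat_series` with fields `times`, `rr`,
#'   `amp` and `record_id`.
#' @export
beat_series <- function(times, amp, record_id = NA_character_) {
  times <- as.numeric(times)
  amp <- as.numeric(amp)
  if (length(amp) != length(times))
    stop("`times` and `amp` must have equal length", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  rr <- if (length(times) > 1L) diff(times) else numeric(0)
  structure(list(times = times, rr = rr, amp = amp,
                 record_id = as.character(record_id)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series '%s': %d beats", x$record_id, length(x$times)))
  if (length(x$rr))
    cat(sprintf(", mean RR %.3f s", mean(x$rr)))
  cat(">\n")
  invisible(x)
}

#' One labeled model-input window
#'
#' A five-minute context window centred on one labeled minute, resampled to
#' two aligned fixed-length channels (RR intervals in seconds and R-peak
#' amplitudes in mV).
#'
#' @param record_id Record identifier.
#' @param center_minute 0-based index of the labeled minute.
#' @param rr_channel,amp_channel Numeric channels of equal fixed length
#'   (900 by default throughout the package).
#' @param label 0 (normal) or 1 (apnea).
#' @return An object of class `segment_window`.
#' @export
segment_window <- function(record_id, center_minute, rr_channel,
                           amp_channel, label) {
  if (length(rr_channel) != length(amp_channel))
    stop("channel lengths differ", call. = FALSE)
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1", call. = FALSE)
  structure(
    list(record_id = as.character(record_id),
         center_minute = as.integer(center_minute),
         rr_channel = as.numeric(rr_channel),
         amp_channel = as.numeric(amp_channel),
         label = label),
    class = "segment_window"
  )
}

#' Respiratory event
#'
#' A scored respiratory event (apnea or hypopnea) in a polysomnogram,
#' positioned in seconds from the start of the recording.
#'
#' @param onset_s Onset in seconds (>= 0).
#' @param duration_s Duration in seconds (> 0).
#' @param event_type Free-text event type (e.g. "APNEA-O", "HYP").
#' @return An object of class `resp_event`.
#' @export
resp_event <- function(onset_s, duration_s, event_type = "APNEA") {
  if (onset_s < 0) stop("`onset_s` must be >= 0", call. = FALSE)
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  structure(list(onset_s = as.numeric(onset_s),
                 duration_s = as.numeric(duration_s),
                 event_type = as.character(event_type)),
            class = "resp_event")
}

# Coerce a list of resp_event / a data.frame into a data.frame with
# columns onset_s, duration_s, event_type; validates signs.
as_event_frame <- function(events) {
  if (is.data.frame(events)) {
    df <- events
  } else if (is.list(events)) {
    if (length(events) == 0L) {
      df <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                       event_type = character(0))
    } else {
      df <- do.call(rbind, lapply(events, function(e) {
        data.frame(onset_s = e$onset_s, duration_s = e$duration_s,
                   event_type = e$event_type)
      }))
    }
  } else stop("`events` must be a data.frame or list of resp_event",
              call. = FALSE)
  need <- c("onset_s", "duration_s", "event_type")
  if (!all(need %in% names(df)))
    stop("events need columns onset_s, duration_s, event_type",
         call. = FALSE)
  if (nrow(df)) {
    if (any(df$onset_s < 0)) stop("negative event onset", call. = FALSE)
    if (any(df$duration_s <= 0)) stop("non-positive event duration",
                                      call. = FALSE)
  }
  df
}
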