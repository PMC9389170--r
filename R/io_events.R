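# Respiratory event tables and the per-minute labeling rule used for
# polysomnogram recordings: a minute is apneic when scored events occupy
# strictly more than 5 seconds of it.

#' Read a respiratory event table
#'
#' Reads a plain-text table of scored respiratory events with columns
#' `onset_s`, `duration_s` and `event_type` (CSV or whitespace-separated,
#' with header).
#'
#' @param path File path.
#' @return A data.frame with the three columns above.
#' @export
read_resp_events <- function(path) {
  if (!file.exists(path))
    stop(sprintf("event file not found: '%s'", path), call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  df <- if (grepl(",", first)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  }
  as_event_frame(df)
}

#' Per-minute labels from respiratory events
#'
#' Labels minute `m` (0-based, covering `[60m, 60(m+1))` seconds) as apneic
#' when the total overlap of the selected events with that minute is
#' strictly greater than `threshold_s` seconds.
#'
#' @param events Respiratory events: a data.frame with columns `onset_s`,
#'   `duration_s`, `event_type`, or a list of [resp_event()] objects.
#' @param n_minutes Number of minutes to label (>= 0).
#' @param include_types Character vector of event types to count, or
#'   `NULL` (default) to count every event in the table. The default
#'   matches labeling pipelines that score all apnea and hypopnea events;
#'   pass a subset to restrict, e.g., to obstructive apneas.
#' @param threshold_s Overlap threshold in seconds; strictly-greater-than
#'   comparison (default 5).
#' @param record_id Identifier stored in the result.
#' @return A [minute_labels()] object of length `n_minutes`.
#' @export
ucddb_minute_labels <- function(events, n_minutes, include_types = NULL,
                                threshold_s = 5,
                                record_id = NA_character_) {
  if (n_minutes < 0) stop("`n_minutes` must be >= 0", call. = FALSE)
  df <- as_event_frame(events)
  if (!is.null(include_types))
    df <- df[df$event_type %in% include_types, , drop = FALSE]
  labels <- integer(n_minutes)
  if (n_minutes > 0L && nrow(df)) {
    # merge events into disjoint occupancy intervals so overlapping
    # scored events are not double-counted
    o <- order(df$onset_s)
    starts <- df$onset_s[o]
    ends <- starts + df$duration_s[o]
    ms <- starts[1L]; me <- ends[1L]
    mstarts <- numeric(0); mends <- numeric(0)
    if (nrow(df) > 1L) for (i in 2:nrow(df)) {
      if (starts[i] <= me) {
        me <- max(me, ends[i])
      } else {
        mstarts <- c(mstarts, ms); mends <- c(mends, me)
        ms <- starts[i]; me <- ends[i]
      }
    }
    mstarts <- c(mstarts, ms); mends <- c(mends, me)
    for (m in seq_len(n_minutes) - 1L) {
      lo <- 60 * m
      hi <- lo + 60
      overlap <- sum(pmax(0, pmin(mends, hi) - pmax(mstarts, lo)))
      labels[m + 1L] <- as.integer(overlap > threshold_s)
    }
  }
  minute_labels(record_id, labels)
}
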