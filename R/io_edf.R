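# Minimal EDF (European Data Format) I/O: fixed 256-byte global header,
# 256 bytes per signal, data records of 16-bit little-endian samples with
# linear digital -> physical scaling. Enough to round-trip polysomnogram
# ECG channels; EDF+ annotation streams are out of scope.

edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n)  # left-justified, space padded
}

read_edf_header <- function(con) {
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  startdate <- rd(8); starttime <- rd(8)
  header_bytes <- as.integer(rd(8)); reserved <- rd(44)
  n_records <- as.integer(rd(8)); record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- trimws(fld(16)); transducer <- fld(80)
  phys_dim <- trimws(fld(8))
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  prefilter <- fld(80); n_samp <- as.integer(fld(8)); fld(32)
  list(n_records = n_records, record_dur = record_dur, ns = ns,
       labels = labels, phys_dim = phys_dim,
       phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max, n_samp = n_samp)
}

#' Read one channel from an EDF file
#'
#' Returns the named signal in physical units at its own sampling rate.
#' Signals whose physical dimension is microvolts are converted to mV;
#' anything else is returned as stored.
#'
#' @param path EDF file path.
#' @param channel_name Signal label as stored in the EDF header
#'   (whitespace-trimmed exact match).
#' @return An [ecg_record()] whose `fs` is the channel's samples per
#'   record divided by the record duration.
#' @export
read_edf_channel <- function(path, channel_name) {
  if (!file.exists(path))
    stop(sprintf("EDF file not found: '%s'", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  idx <- match(channel_name, h$labels)
  if (is.na(idx))
    stop(sprintf("channel '%s' not in EDF file; available: %s",
                 channel_name, paste(h$labels, collapse = ", ")),
         call. = FALSE)
  per_rec <- h$n_samp
  out <- numeric(h$n_records * per_rec[idx])
  pos <- 0L
  for (r in seq_len(h$n_records)) {
    for (s in seq_len(h$ns)) {
      vals <- readBin(con, "integer", n = per_rec[s], size = 2L,
                      signed = TRUE, endian = "little")
      if (length(vals) < per_rec[s])
        stop(sprintf("truncated EDF data in '%s'", path), call. = FALSE)
      if (s == idx) {
        out[pos + seq_len(per_rec[s])] <- vals
        pos <- pos + per_rec[s]
      }
    }
  }
  scale <- (h$phys_max[idx] - h$phys_min[idx]) /
    (h$dig_max[idx] - h$dig_min[idx])
  phys <- h$phys_min[idx] + (out - h$dig_min[idx]) * scale
  if (identical(tolower(h$phys_dim[idx]), "uv")) phys <- phys / 1000
  fs <- per_rec[idx] / h$record_dur
  ecg_record(sub("\\.edf$", "", basename(path), ignore.case = TRUE),
             fs, phys)
}

#' Write a minimal EDF file
#'
#' Companion writer for [read_edf_channel()]; used by the test fixtures.
#' Each signal is a list with `label`, `fs` (Hz) and `x` (numeric samples,
#' physical units, assumed mV). All signals must span the same whole
#' number of seconds; data records are one second long.
#'
#' @param path Output path.
#' @param signals List of signal descriptions (see above).
#' @param phys_dim Physical dimension string stored per signal.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(path, signals, phys_dim = "mV") {
  ns <- length(signals)
  dur <- vapply(signals, function(s) length(s$x) / s$fs, numeric(1))
  if (length(unique(round(dur, 9))) != 1L || any(dur != round(dur)))
    stop("all signals must span the same whole number of seconds",
         call. = FALSE)
  n_records <- as.integer(dur[1L])
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeBin(charToRaw(edf_pad(x, n)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (1L + ns), 8); wr("", 44)
  wr(n_records, 8); wr(1, 8); wr(ns, 4)
  pm <- lapply(signals, function(s) {
    m <- max(abs(s$x), 1e-6)
    c(-m, m)
  })
  for (s in signals) wr(s$label, 16)
  for (s in signals) wr("", 80)
  for (s in signals) wr(phys_dim, 8)
  for (p in pm) wr(format(p[1], digits = 6), 8)
  for (p in pm) wr(format(p[2], digits = 6), 8)
  for (s in signals) wr(-32768L, 8)
  for (s in signals) wr(32767L, 8)
  for (s in signals) wr("", 80)
  for (s in signals) wr(as.integer(s$fs), 8)
  for (s in signals) wr("", 32)
  for (r in seq_len(n_records)) {
    for (k in seq_len(ns)) {
      s <- signals[[k]]
      seg <- s$x[((r - 1L) * s$fs + 1L):(r * s$fs)]
      dig <- round((seg - pm[[k]][1]) / (pm[[k]][2] - pm[[k]][1]) *
                     65535) - 32768
      writeBin(as.integer(pmax(pmin(dig, 32767), -32768)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}
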