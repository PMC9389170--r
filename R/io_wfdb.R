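# Minimal WFDB format-16 signal I/O and plain-text per-minute apnea
# annotations. Only what the pipeline touches: single- or multi-channel
# 16-bit little-endian sample files with gain/baseline scaling to mV.

#' Read a WFDB record
#'
#' Reads a WFDB header (`.hea`) plus its 16-bit sample file (`.dat`) and
#' returns one channel in physical units (mV). Only signal format 16
#' (16-bit little-endian, interleaved channels) is supported, which covers
#' the records written by [write_wfdb_record()] and the common
#' single-lead ECG benchmark layout.
#'
#' @param path Path to the record: either the `.hea` file or the record
#'   name without extension.
#' @param channel 1-based channel index.
#' @return An [ecg_record()] in mV, with `fs` taken from the header.
#' @export
read_wfdb_record <- function(path, channel = 1L) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea))
    stop(sprintf("WFDB header not found: '%s'", hea), call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L)
    stop(sprintf("malformed WFDB header '%s'", hea), call. = FALSE)
  head_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(head_tok) < 4L)
    stop(sprintf("malformed WFDB header line in '%s'", hea), call. = FALSE)
  record_id <- head_tok[1L]
  n_sig <- as.integer(head_tok[2L])
  fs <- as.numeric(strsplit(head_tok[3L], "/")[[1L]][1L])  # strip counter rate
  n_samp <- as.integer(head_tok[4L])
  if (is.na(n_sig) || is.na(fs) || is.na(n_samp))
    stop(sprintf("malformed WFDB header '%s'", hea), call. = FALSE)
  if (!is.numeric(channel) || length(channel) != 1L ||
      channel < 1L || channel > n_sig)
    stop(sprintf("channel %s out of range: record has %d signal(s)",
                 as.character(channel), n_sig), call. = FALSE)

  sig_tok <- strsplit(trimws(lines[1L + channel]), "\\s+")[[1L]]
  dat_file <- sig_tok[1L]
  fmt <- sub("x.*$", "", sig_tok[2L])  # ignore samples-per-frame suffix
  if (fmt != "16")
    stop(sprintf("unsupported WFDB signal format '%s' (only 16)", fmt),
         call. = FALSE)
  # gain spec: GAIN, GAIN(BASELINE), GAIN/UNITS, GAIN(BASELINE)/UNITS
  gain_spec <- if (length(sig_tok) >= 3L) sig_tok[3L] else "200"
  units <- if (grepl("/", gain_spec)) sub("^[^/]*/", "", gain_spec) else "mV"
  gb <- sub("/.*$", "", gain_spec)
  baseline <- 0
  if (grepl("\\(", gb)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", gb))
    gb <- sub("\\(.*$", "", gb)
  }
  gain <- as.numeric(gb)
  if (is.na(gain) || gain == 0) gain <- 200  # WFDB default adu/mV

  dat <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat))
    stop(sprintf("WFDB signal file not found: '%s'", dat), call. = FALSE)
  n_expected <- n_sig * n_samp
  raw <- readBin(dat, "integer", n = n_expected, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(raw) < n_expected)
    stop(sprintf("truncated WFDB signal file '%s': %d of %d samples",
                 dat, length(raw), n_expected), call. = FALSE)
  adu <- raw[seq.int(channel, by = n_sig, length.out = n_samp)]
  phys <- (adu - baseline) / gain
  if (identical(tolower(units), "uv")) phys <- phys / 1000
  ecg_record(record_id, fs, phys)
}

#' Write a WFDB record
#'
#' Writes an [ecg_record()] as a WFDB format-16 pair (`<id>.hea`,
#' `<id>.dat`) with a fixed gain, quantizing samples to 16-bit integers.
#'
#' @param rec An `ecg_record` (signal in mV).
#' @param dir Output directory (created if needed).
#' @param gain ADC units per mV (default 200, the conventional ECG gain).
#' @return Invisibly, the path of the header file.
#' @export
write_wfdb_record <- function(rec, dir, gain = 200) {
  stopifnot(inherits(rec, "ecg_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  adu <- as.integer(pmax(pmin(round(rec$signal * gain), 32767), -32768))
  hea <- file.path(dir, paste0(rec$record_id, ".hea"))
  dat_name <- paste0(rec$record_id, ".dat")
  writeLines(c(
    sprintf("%s 1 %g %d", rec$record_id, rec$fs, length(adu)),
    sprintf("%s 16 %g/mV 16 0 %d 0 0 ECG", dat_name, gain,
            if (length(adu)) adu[1L] else 0L)
  ), hea)
  writeBin(adu, file.path(dir, dat_name), size = 2L, endian = "little")
  invisible(hea)
}

#' Read per-minute apnea annotations
#'
#' Reads a plain-text annotation stream with one mark per line: `A` for an
#' apneic minute, `N` for a normal one. Mark `i` labels minute `i - 1`
#' (0-based minutes).
#'
#' @param path Annotation file path.
#' @param record_id Identifier stored in the result; defaults to the file
#'   base name.
#' @return A [minute_labels()] object (empty file gives zero minutes).
#' @export
read_apnea_minute_labels <- function(path,
                                     record_id = sub("\\..*$", "",
                                                     basename(path))) {
  if (!file.exists(path))
    stop(sprintf("annotation file not found: '%s'", path), call. = FALSE)
  marks <- trimws(readLines(path, warn = FALSE))
  marks <- marks[nzchar(marks)]
  if (!length(marks)) return(minute_labels(record_id, integer(0)))
  bad <- setdiff(unique(marks), c("A", "N"))
  if (length(bad))
    stop(sprintf("unknown annotation mark(s) in '%s': %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  minute_labels(record_id, as.integer(marks == "A"))
}

#' Write per-minute apnea annotations
#'
#' Companion writer for [read_apnea_minute_labels()]: one `A`/`N` mark per
#' line, minute order.
#'
#' @param labels A `minute_labels` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_apnea_minute_labels <- function(labels, path) {
  stopifnot(inherits(labels, "minute_labels"))
  writeLines(ifelse(labels$labels == 1L, "A", "N"), path)
  invisible(path)
}

#' Export minute labels as CSV
#'
#' @param labels A `minute_labels` object.
#' @param path Output CSV path; columns `minute` (0-based) and `label`.
#' @return Invisibly, `path`.
#' @export
write_minute_labels_csv <- function(labels, path) {
  stopifnot(inherits(labels, "minute_labels"))
  utils::write.csv(
    data.frame(minute = seq_along(labels$labels) - 1L,
               label = labels$labels),
    path, row.names = FALSE)
  invisible(path)
}
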