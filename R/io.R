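#' Read a single-channel EEG recording
#'
#' Supports European Data Format (EDF) and two-column tab-separated text
#' (`time_s`, `amplitude_uV`, with header). The sampling rate is taken
#' from the EDF header, or inferred from the median time step of the TSV
#' time column; TSV timestamps must be uniform to within 1 ppm of the
#' sampling interval.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"edf"` or `"tsv"`.
#' @param label Optional label; defaults to the file name.
#' @return An [recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "tsv"),
                           label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  if (is.null(label)) label <- basename(path)
  if (format == "edf") read_edf(path, label) else read_tsv_recording(path, label)
}

read_tsv_recording <- function(path, label) {
  d <- tryCatch(read.table(path, header = TRUE, sep = "\t"),
                error = function(e) stop_input("malformed TSV file %s: %s",
                                               path, conditionMessage(e)))
  if (ncol(d) < 2L)
    stop_input("TSV recording must have two columns (time_s, amplitude_uV)")
  t <- d[[1L]]
  x <- d[[2L]]
  if (length(t) < 2L) stop_input("TSV recording must have at least 2 samples")
  dt <- diff(t)
  step <- median(dt)
  if (step <= 0 || any(abs(dt - step) > 1e-6 * step))
    stop_input("non-uniform sampling in %s (tolerance 1 ppm)", path)
  recording(x, fs = 1 / step, start_time = t[1L], label = label)
}

#' Write a recording as two-column TSV
#'
#' @param rec An [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  d <- data.frame(time_s = sprintf("%.9g", sample_times(rec)),
                  amplitude_uV = sprintf("%.9g", rec$samples))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- Minimal EDF support -----------------------------------------------
# EDF stores fixed-length ASCII headers followed by 16-bit little-endian
# samples, mapped linearly from digital to physical range. Only
# single-channel continuous recordings are needed here; the writer pads
# the final data record with zeros when the recording does not fill it.

edf_pad <- function(s, width) formatC(as.character(s), width = width,
                                      flag = "-")

#' Write a recording to an EDF file
#'
#' Minimal single-channel EDF writer (1 s data records, 16-bit samples,
#' physical range from the data). The last record is zero-padded when the
#' recording length is not a whole number of seconds.
#'
#' @param rec An [recording()]; `fs` must be a whole number.
#' @param path Output path.
#' @param physical_dim Physical dimension string (default "uV").
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_dim = "uV") {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop_input("EDF writer requires an integer sampling rate (got %g)", fs)
  fs <- as.integer(round(fs))
  x <- rec$samples
  n_rec <- ceiling(length(x) / fs)
  pad <- n_rec * fs - length(x)
  pmax_v <- max(abs(x), 1)
  dig <- as.integer(round(c(x, numeric(pad)) / pmax_v * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(paste("Startdate X X X", substr(rec$label, 1, 40)), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256, 8),            # header bytes: global + 1 signal
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),                  # record duration (s)
    edf_pad("1", 4),                  # number of signals
    # per-signal fields
    edf_pad(substr(paste("EEG", rec$label), 1, 16), 16),
    edf_pad("", 80),
    edf_pad(physical_dim, 8),
    edf_pad(sprintf("%.6g", -pmax_v), 8),
    edf_pad(sprintf("%.6g", pmax_v), 8),
    edf_pad("-32768", 8), edf_pad("32767", 8),
    edf_pad("", 80),
    edf_pad(fs, 8),
    edf_pad("", 32))
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

read_edf <- function(path, label) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) {
    out <- readChar(con, nchars, useBytes = TRUE)
    if (length(out) == 0L || nchar(out) < nchars)
      stop_input("malformed EDF header in %s (truncated)", path)
    trimws(out)
  }
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(header_bytes, n_rec, rec_dur, ns)) || ns < 1L || rec_dur <= 0)
    stop_input("malformed EDF header in %s", path)
  if (ns > 1L)
    warning(sprintf("EDF file has %d signals; reading the first only", ns))
  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  fld(16); fld(80)
  phys_dim <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- suppressWarnings(as.integer(fld(8)))
  fld(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr)))
    stop_input("malformed EDF signal header in %s", path)
  seek(con, header_bytes)
  total <- sum(spr)
  out <- numeric(n_rec * spr[1L])
  scale <- (phys_max[1L] - phys_min[1L]) / (dig_max[1L] - dig_min[1L])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                     endian = "little")
    if (length(block) < total)
      stop_input("EDF data truncated in %s (record %d)", path, r)
    d <- block[seq_len(spr[1L])]
    out[((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <-
      phys_min[1L] + (d - dig_min[1L]) * scale
  }
  recording(out, fs = spr[1L] / rec_dur, label = label)
}

#' Write an event list as tab-separated text
#'
#' Columns: `label`, `start_s`, `end_s`, `duration_s` (0-based times,
#' half-open intervals).
#'
#' @param events Event data frame (`label`, `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  d <- data.frame(label = events$label,
                  start_s = sprintf("%.6f", events$start),
                  end_s = sprintf("%.6f", events$end),
                  duration_s = sprintf("%.6f", events$end - events$start))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
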