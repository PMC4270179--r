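#' Peak-to-peak amplitude of a segment
#'
#' Absolute difference between the maximum and minimum voltage within an
#' individual burst or suppression.
#'
#' @param x Numeric vector of voltage samples (uV), nonempty.
#' @return Peak-to-peak amplitude in uV (>= 0).
#' @export
peak_to_peak <- function(x) {
  if (!length(x)) stop_input("segment is empty")
  max(x) - min(x)
}

#' Event power in dB
#'
#' Power of an individual burst or suppression: the summed squared
#' amplitude divided by the event's own duration, in decibels
#' (`10 * log10(sum(x^2) / T)`, reported as dB uV^2/s). An all-zero
#' segment has undefined (-Inf) power and is reported as missing with a
#' warning.
#'
#' @param x Numeric vector of voltage samples (uV), nonempty.
#' @param fs Sampling rate in Hz (> 0).
#' @return Power in dB, or `NA` for an all-zero segment.
#' @export
event_power_db <- function(x, fs) {
  if (!length(x)) stop_input("segment is empty")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_input("'fs' must be a single positive number")
  ss <- sum(x^2)
  if (ss == 0) {
    warning("all-zero segment has undefined (-Inf) power; returning NA")
    return(NA_real_)
  }
  10 * log10(ss / (length(x) / fs))
}

#' Mean BSP over an event
#'
#' Arithmetic mean of the smoothed BSP over the samples covered by the
#' event's half-open `[start, end)` interval.
#'
#' @param event One-row event (list or data frame row with `start`,
#'   `end` in seconds).
#' @param trace A [bsp()] fit whose binary series spans the event.
#' @param start_time Time of the trace's first step (s).
#' @return Mean BSP in \[0, 1\].
#' @export
assign_bsp <- function(event, trace, start_time = 0) {
  stopifnot(inherits(trace, "bsp"))
  delta <- trace$binary$delta
  n <- length(trace$bsp)
  i0 <- floor((event$start - start_time) / delta) + 1
  i1 <- ceiling((event$end - start_time) / delta)
  if (i0 < 1 || i1 > n + 1e-9 || i1 < i0)
    stop_input("event [%g, %g) lies outside the BSP trace span",
               event$start, event$end)
  mean(trace$bsp[i0:min(i1, n)])
}

bsp_bin_breaks <- c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
bsp_bin_labels <- c("0.3-0.4", "0.4-0.5", "0.5-0.6", "0.6-0.7", "0.7-0.8")

#' Assign BSP bins to events
#'
#' Sorts events into BSP bins 0.3-0.4, 0.4-0.5, 0.5-0.6, 0.6-0.7 and
#' 0.7-0.8 by their mean BSP. Bins are half-open `[lo, hi)` with the top
#' bin closed at 0.8; events outside 0.3-0.8 get bin `"none"` and are
#' excluded from comparisons.
#'
#' @param mean_bsp Numeric vector of mean BSP values.
#' @return Character vector of bin labels.
#' @export
bsp_bin <- function(mean_bsp) {
  idx <- findInterval(mean_bsp, bsp_bin_breaks, rightmost.closed = TRUE)
  out <- rep("none", length(mean_bsp))
  ok <- idx >= 1 & idx <= length(bsp_bin_labels)
  out[ok] <- bsp_bin_labels[idx[ok]]
  out
}

#' Per-event feature table
#'
#' Computes duration, peak-to-peak amplitude, power, mean BSP and BSP bin
#' for every event retained after minimum-duration filtering. Features
#' are measured on the conditioned (band-passed, resampled, detrended but
#' unsmoothed) recording.
#'
#' @param rec The conditioned [recording()].
#' @param events Event data frame (already duration-filtered).
#' @param trace A [bsp()] fit aligned with the recording.
#' @return Data frame with columns `label`, `start`, `end`, `duration`,
#'   `p2p`, `power_db`, `mean_bsp`, `bin`.
#' @export
event_features <- function(rec, events, trace) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(trace, "bsp"))
  n <- nrow(events)
  p2p <- power <- mbsp <- numeric(n)
  for (k in seq_len(n)) {
    i0 <- floor((events$start[k] - rec$start_time) * rec$fs) + 1
    i1 <- ceiling((events$end[k] - rec$start_time) * rec$fs)
    seg <- rec$samples[max(1, i0):min(length(rec$samples), i1)]
    p2p[k] <- peak_to_peak(seg)
    power[k] <- suppressWarnings(event_power_db(seg, rec$fs))
    mbsp[k] <- assign_bsp(events[k, ], trace, rec$start_time)
  }
  data.frame(label = events$label, start = events$start, end = events$end,
             duration = events$end - events$start,
             p2p = p2p, power_db = power, mean_bsp = mbsp,
             bin = bsp_bin(mbsp), stringsAsFactors = FALSE)
}

#' Event counts per BSP bin
#'
#' Tabulates bursts and suppressions per BSP bin for one or more
#' conditions, with totals — the layout of a per-anesthetic sorted-event
#' count table.
#'
#' @param ... Named event-feature data frames (one per condition), as
#'   returned by [event_features()].
#' @return Data frame: one row per bin plus a `Total` row; per condition,
#'   columns `<name>_bursts` and `<name>_suppressions`.
#' @export
bin_count_table <- function(...) {
  conds <- list(...)
  if (is.null(names(conds)) || any(!nzchar(names(conds))))
    stop_input("each condition must be named")
  out <- data.frame(bin = c(bsp_bin_labels, "Total"), stringsAsFactors = FALSE)
  for (nm in names(conds)) {
    fx <- conds[[nm]]
    for (lab in c("bursts", "suppressions")) {
      evlab <- sub("s$", "", lab)
      counts <- vapply(bsp_bin_labels, function(b)
        sum(fx$bin == b & fx$label == evlab), integer(1))
      out[[paste(nm, lab, sep = "_")]] <- c(counts, sum(counts))
    }
  }
  out
}
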