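#' Construct a single-channel EEG recording
#'
#' A recording is a uniformly sampled single-channel voltage trace in
#' microvolts with a sampling rate in Hz. All analysis functions in
#' burstkit operate on this container.
#'
#' @param samples Numeric vector of voltage samples (uV).
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#' @param label Optional text label (e.g. the condition name).
#' @return An object of class `eeg_recording`: a list with elements
#'   `samples`, `fs`, `start_time`, `label`.
#' @examples
#' rec <- recording(sin(2 * pi * 5 * seq(0, 1, by = 1 / 250)), fs = 250)
#' duration(rec)
#' @export
recording <- function(samples, fs, start_time = 0, label = "") {
  if (!is.numeric(samples)) stop_input("'samples' must be numeric")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop_input("'samples' must be finite and non-missing")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_input("'fs' must be a single positive number")
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 start_time = as.numeric(start_time),
                 label = as.character(label)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording%s: %d samples @ %g Hz, %.2f s>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$samples), x$fs, duration(x)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds (`n_samples / fs`).
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  length(rec$samples) / rec$fs
}

#' Sample times of a recording
#' @param rec An `eeg_recording`.
#' @return Numeric vector of sample times (s), starting at `start_time`.
#' @export
sample_times <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  rec$start_time + (seq_along(rec$samples) - 1L) / rec$fs
}

#' @export
plot.eeg_recording <- function(x, ...,
                               xlab = "time (s)", ylab = "amplitude (uV)") {
  plot(sample_times(x), x$samples, type = "l",
       xlab = xlab, ylab = ylab, main = x$label, ...)
  invisible(x)
}
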