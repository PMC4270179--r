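#' Nonlinear energy operator (Kaiser)
#'
#' Computes the instantaneous energy
#' `psi(n) = x(n)^2 - x(n-1) * x(n+1)` at interior samples; boundary
#' samples copy the nearest interior value, so the output has the same
#' length as the input. The operator responds to both amplitude and
#' frequency, which separates high-energy bursts cleanly from low-energy
#' suppressions.
#'
#' @param rec An [recording()] with at least 3 samples.
#' @param smooth_sigma Optional Gaussian smoothing (seconds) applied to
#'   the energy sequence itself; `NULL` (default) leaves it raw.
#' @return An object of class `energy_series`: list with `values` (uV^2)
#'   and `fs` (Hz), same length as the recording.
#' @export
nleo <- function(rec, smooth_sigma = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$samples
  n <- length(x)
  if (n < 3L) stop_input("the nonlinear energy operator needs >= 3 samples")
  psi <- numeric(n)
  i <- 2:(n - 1L)
  psi[i] <- x[i]^2 - x[i - 1L] * x[i + 1L]
  psi[1L] <- psi[2L]
  psi[n] <- psi[n - 1L]
  if (!is.null(smooth_sigma))
    psi <- gaussian_smooth_vec(psi, smooth_sigma, rec$fs)
  structure(list(values = psi, fs = rec$fs, start_time = rec$start_time),
            class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("<energy_series: %d samples @ %g Hz, median %.3g uV^2>\n",
              length(x$values), x$fs, median(x$values)))
  invisible(x)
}

#' Threshold an energy series into burst/suppression labels
#'
#' Samples with energy above the threshold are bursts, the rest
#' suppressions.
#'
#' @param energy An `energy_series` from [nleo()].
#' @param theta Energy threshold in uV^2 (> 0).
#' @return Character vector of labels, `"burst"` or `"suppression"`.
#' @export
threshold_labels <- function(energy, theta) {
  stopifnot(inherits(energy, "energy_series"))
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stop_input("'theta' must be a single positive energy value")
  ifelse(energy$values > theta, "burst", "suppression")
}

#' Suggest an energy threshold
#'
#' The reference procedure sets the energy threshold by visual
#' inspection; for unattended use this splits the (roughly bimodal)
#' log-energy distribution. A two-component Gaussian mixture is fitted
#' to the strictly positive energies on the log scale
#' (`mclust::Mclust`, unequal variances); the threshold is the larger of
#' the equal-posterior crossing and the lower 3-sigma tail of the
#' high-energy component, clamped between the component means. The tail
#' guard matters because suppression log-energy is right-skewed, which
#' otherwise pulls the crossing too low. If the mixture cannot be
#' fitted, the Otsu
#' (between-class variance) criterion on the log-energy histogram is
#' used instead. If the energy is degenerate (essentially constant), a
#' warning is raised and the midpoint of the log-energy range is
#' returned.
#'
#' @param energy An `energy_series` from [nleo()].
#' @param method `"mixture"` (default) or `"otsu"`.
#' @param n_bins Histogram bins for the Otsu criterion.
#' @param max_points Subsample cap for the mixture fit.
#' @return Threshold in uV^2.
#' @export
suggest_threshold <- function(energy, method = c("mixture", "otsu"),
                              n_bins = 512L, max_points = 20000L) {
  stopifnot(inherits(energy, "energy_series"))
  method <- match.arg(method)
  v <- energy$values[energy$values > 0]
  if (length(v) < 10L || diff(range(log(v))) < 1e-8) {
    warning("energy series is degenerate (single regime); returning midpoint of log-energy range")
    vv <- pmax(energy$values, 0)
    eps <- max(vv) * 1e-12 + .Machine$double.xmin
    return(exp(mean(range(log(vv + eps)))))
  }
  lv <- log(v)
  if (method == "mixture") {
    th <- tryCatch(mixture_split(lv, max_points), error = function(e) NULL)
    if (!is.null(th) && is.finite(th)) return(exp(th))
    method <- "otsu"
  }
  exp(otsu_split(lv, n_bins))
}

# Decision boundary from a 2-component Gaussian mixture fitted to x
# (unequal variances). The boundary is the larger of (a) the
# equal-posterior crossing between the component means and (b) the lower
# 3-sigma tail of the high-energy (burst) component, clamped between
# the means: (b) protects against the skewed right tail of the
# suppression component on the log scale pulling the crossing too low.
mixture_split <- function(x, max_points) {
  if (length(x) > max_points)
    x <- x[round(seq(1L, length(x), length.out = max_points))]
  # deterministic initialization subset: mclust otherwise draws a random
  # one, which would break bit-reproducibility of the pipeline
  sub <- round(seq(1L, length(x), length.out = min(length(x), 1000L)))
  fit <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE,
               initialization = list(subset = sub))
  if (is.null(fit)) stop("mixture fit failed")
  mu <- fit$parameters$mean
  s <- sqrt(fit$parameters$variance$sigmasq)
  if (length(s) == 1L) s <- rep(s, 2L)
  w <- fit$parameters$pro
  o <- order(mu)
  mu <- mu[o]; s <- s[o]; w <- w[o]
  if (diff(mu) < 1e-6) stop("mixture components collapsed")
  f <- function(z) w[1] * stats::dnorm(z, mu[1], s[1]) -
    w[2] * stats::dnorm(z, mu[2], s[2])
  cross <- if (sign(f(mu[1])) == sign(f(mu[2]))) mean(mu)
           else stats::uniroot(f, c(mu[1], mu[2]))$root
  min(max(cross, mu[2] - 3 * s[2], mu[1]), mu[2])
}

# Otsu's between-class variance criterion on a histogram of x.
otsu_split <- function(x, n_bins) {
  rng <- range(x)
  h <- hist(x, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mu <- cumsum(w * h$mids)
  omega <- cumsum(w)
  mu_t <- mu[length(mu)]
  valid <- omega > 1e-12 & omega < 1 - 1e-12
  between <- rep(-Inf, length(w))
  between[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  h$breaks[which.max(between) + 1L]
}

#' Merge sub-threshold label runs into their surroundings
#'
#' Iteratively relabels interior runs shorter than `min_dur` (shortest
#' first), merging them into the surrounding event. Brief energy dips
#' inside a burst (or blips inside a suppression) otherwise fragment
#' long events into spurious short ones. Edge runs are left untouched.
#'
#' @param labels Character vector of `"burst"`/`"suppression"`.
#' @param fs Sampling rate of the labels in Hz.
#' @param min_dur Minimum run duration retained (s).
#' @return The cleaned label vector.
#' @export
merge_short_runs <- function(labels, fs, min_dur = 0.15) {
  if (!length(labels)) stop_input("'labels' must be nonempty")
  min_len <- ceiling(min_dur * fs)
  repeat {
    r <- rle(as.character(labels))
    k <- seq_along(r$lengths)
    short <- k[r$lengths < min_len & k > 1L & k < length(k)]
    if (!length(short)) break
    j <- short[which.min(r$lengths[short])]
    r$values[j] <- if (r$values[j] == "burst") "suppression" else "burst"
    labels <- inverse.rle(r)
  }
  labels
}

#' Run-length encode labels into events
#'
#' Converts a per-sample label sequence into maximal alternating events
#' tiling the analyzed span with half-open `[start, end)` intervals.
#'
#' @param labels Character vector of `"burst"`/`"suppression"`.
#' @param fs Sampling rate of the labels in Hz.
#' @param start_time Time of the first sample (s).
#' @return Data frame with columns `label`, `start`, `end` (s).
#' @export
events_from_labels <- function(labels, fs, start_time = 0) {
  if (!length(labels)) stop_input("'labels' must be nonempty")
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths) / fs + start_time
  starts <- c(start_time, ends[-length(ends)])
  data.frame(label = r$values, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Discard events shorter than a minimum duration
#'
#' Events shorter than `min_dur` (default 0.15 s) are too brief to
#' constitute a clear burst or suppression and are dropped from feature
#' statistics. The rule is strict (`duration < min_dur` is discarded, an
#' exact 0.15 s event is retained). The binary series used for BSP
#' estimation is built from the unfiltered labels, not from this list.
#'
#' @param events Event data frame.
#' @param min_dur Minimum duration in seconds (>= 0).
#' @return The retained events.
#' @export
filter_min_duration <- function(events, min_dur = 0.15) {
  if (min_dur < 0) stop_input("'min_dur' must be >= 0")
  keep <- (events$end - events$start) >= min_dur - 1e-12
  events[keep, , drop = FALSE]
}

#' Binary suppression series
#'
#' Container for a per-sample suppression indicator at fixed interval
#' `delta`: 1 = suppression, 0 = burst, so that a BSP of 1 corresponds to
#' complete EEG suppression.
#'
#' @param values Vector of 0/1 indicators.
#' @param delta Sampling interval in seconds (> 0).
#' @return An object of class `binary_series`.
#' @export
binary_series <- function(values, delta) {
  if (!length(values) || !all(values %in% c(0, 1)))
    stop_input("'values' must be a nonempty 0/1 vector")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop_input("'delta' must be a single positive interval (seconds)")
  structure(list(values = as.integer(values), delta = as.numeric(delta)),
            class = "binary_series")
}

#' @export
print.binary_series <- function(x, ...) {
  cat(sprintf("<binary_series: %d steps @ %g s, suppression fraction %.3f>\n",
              length(x$values), x$delta, mean(x$values)))
  invisible(x)
}

#' Binarize burst/suppression labels
#'
#' Suppression samples become 1, burst samples 0, at interval
#' `delta = 1/fs`.
#'
#' @param labels Character vector of `"burst"`/`"suppression"`.
#' @param fs Sampling rate in Hz.
#' @return A [binary_series()].
#' @export
binarize <- function(labels, fs) {
  if (!length(labels)) stop_input("'labels' must be nonempty")
  binary_series(as.integer(labels == "suppression"), 1 / fs)
}

#' Segment a recording into bursts and suppressions
#'
#' Full segmentation chain on an already-conditioned recording: Gaussian
#' smoothing, nonlinear energy operator (optionally smoothed), energy
#' threshold (automatic by default, or a manual value), run-length
#' events, minimum-duration filtering for feature statistics, and the
#' binary suppression series for BSP estimation.
#'
#' @param rec A conditioned [recording()] (band-passed, resampled,
#'   detrended).
#' @param threshold `"auto"` (default, [suggest_threshold()]) or a
#'   positive energy value in uV^2.
#' @param smooth_sigma Gaussian smoothing of the EEG before the energy
#'   operator, in seconds (`NULL` to skip).
#' @param energy_smooth_sigma Gaussian smoothing of the energy sequence,
#'   in seconds (`NULL` to skip).
#' @param min_dur Minimum event duration retained for features (s); also
#'   the run length below which [merge_short_runs()] merges label runs
#'   before events are built.
#' @return An object of class `bs_segmentation`: list with `labels` (raw
#'   per-sample labels), `labels_clean` (after [merge_short_runs()]),
#'   `events` (from the cleaned labels), `events_filtered`
#'   (>= `min_dur`), `binary` ([binary_series()] from the raw labels, so
#'   sub-`min_dur` structure is retained for BSP estimation), `energy`,
#'   `threshold`, `fs`.
#' @export
segment_recording <- function(rec, threshold = "auto", smooth_sigma = 0.02,
                              energy_smooth_sigma = 0.04, min_dur = 0.15) {
  stopifnot(inherits(rec, "eeg_recording"))
  sm <- if (is.null(smooth_sigma)) rec else gaussian_smooth(rec, smooth_sigma)
  energy <- nleo(sm, smooth_sigma = energy_smooth_sigma)
  theta <- if (identical(threshold, "auto")) suggest_threshold(energy)
           else threshold
  labels <- threshold_labels(energy, theta)
  labels_clean <- merge_short_runs(labels, rec$fs, min_dur)
  events <- events_from_labels(labels_clean, rec$fs, rec$start_time)
  structure(list(labels = labels,
                 labels_clean = labels_clean,
                 events = events,
                 events_filtered = filter_min_duration(events, min_dur),
                 binary = binarize(labels, rec$fs),
                 energy = energy,
                 threshold = theta,
                 fs = rec$fs),
            class = "bs_segmentation")
}

#' @export
print.bs_segmentation <- function(x, ...) {
  nb <- sum(x$events_filtered$label == "burst")
  ns <- sum(x$events_filtered$label == "suppression")
  cat(sprintf("<bs_segmentation: threshold %.3g uV^2, %d bursts / %d suppressions (>= min duration), suppression fraction %.3f>\n",
              x$threshold, nb, ns, mean(x$binary$values)))
  invisible(x)
}
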