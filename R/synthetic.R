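#' Sample an alternating renewal sequence of bursts and suppressions
#'
#' Draws alternating burst/suppression sojourn times from the profile's
#' gamma duration distributions until `total_duration` is covered; the
#' final event is truncated at `total_duration`. The first event is a
#' burst by default (deterministic), optionally randomized.
#'
#' @param profile A [drug_profile()].
#' @param total_duration Total span to tile, in seconds (> 0).
#' @param seed Integer seed; same seed reproduces the same events.
#' @param first First event label, `"burst"` (default) or `"random"`.
#' @param depth_range Optional length-2 vector `c(f0, f1)`: the target
#'   suppression time fraction drifts linearly from `f0` to `f1` across
#'   the recording (emulating deepening anesthesia) by rescaling the
#'   mean suppression duration; `NULL` (default) keeps the process
#'   stationary at the profile's own fraction.
#' @return A data frame with columns `label` ("burst"/"suppression"),
#'   `start`, `end` (seconds, half-open intervals tiling
#'   `[0, total_duration)`).
#' @export
sample_alternating_renewal <- function(profile, total_duration, seed = NULL,
                                       first = c("burst", "random"),
                                       depth_range = NULL) {
  stopifnot(inherits(profile, "drug_profile"))
  first <- match.arg(first)
  if (!is.numeric(total_duration) || length(total_duration) != 1L ||
      !is.finite(total_duration) || total_duration <= 0)
    stop_input("'total_duration' must be a single positive number (seconds)")
  if (!is.null(depth_range) &&
      (length(depth_range) != 2L || any(depth_range <= 0 | depth_range >= 1)))
    stop_input("'depth_range' must be two fractions strictly inside (0, 1)")
  pm <- profile_means(profile)
  with_seed(seed, {
    if (first == "random") first <- sample(c("burst", "suppression"), 1L)
    lab <- first
    labels <- character(0)
    starts <- numeric(0)
    t <- 0
    while (t < total_duration) {
      # deepening anesthesia lengthens suppressions and shortens bursts;
      # scale the two mean durations by r and 1/r so the local
      # suppression fraction hits its target while cycle lengths stay
      # bounded
      r <- 1
      if (!is.null(depth_range)) {
        f <- depth_fraction(t, total_duration, depth_range)
        odds_base <- pm$supp_fraction / (1 - pm$supp_fraction)
        r <- sqrt((f / (1 - f)) / odds_base)
      }
      d <- if (lab == "burst")
        rgamma(1L, shape = profile$burst_dur_shape,
               scale = profile$burst_dur_scale / r)
      else
        rgamma(1L, shape = profile$supp_dur_shape,
               scale = profile$supp_dur_scale * r)
      labels <- c(labels, lab)
      starts <- c(starts, t)
      t <- t + d
      lab <- if (lab == "burst") "suppression" else "burst"
    }
    ends <- c(starts[-1L], min(t, total_duration))
    ends[length(ends)] <- total_duration
    data.frame(label = labels, start = starts, end = pmin(ends, total_duration),
               stringsAsFactors = FALSE)
  })
}

depth_fraction <- function(t, total, depth_range) {
  depth_range[1] + (depth_range[2] - depth_range[1]) * pmin(t / total, 1)
}

#' Render a burst-suppression waveform from an event sequence
#'
#' Bursts are band-limited oscillatory activity scaled to the profile's
#' burst RMS; suppressions are low-pass background noise at the
#' suppression RMS. The two processes are generated over the whole span
#' and mixed with a raised-cosine transition mask of length
#' `taper_time`, avoiding hard edges that would create segmentation
#' artifacts.
#'
#' With `envelope = "stabilized"` (default) the burst process is
#' band-limited noise normalized by its analytic-signal (Hilbert)
#' envelope: a sustained oscillation with wandering instantaneous
#' frequency inside the band, mimicking the sustained high-amplitude
#' character of anesthetic bursts. `envelope = "gaussian"` keeps the raw
#' band-limited Gaussian noise, whose Rayleigh-fading envelope
#' periodically dips to zero even inside a burst.
#'
#' @param events Event data frame from [sample_alternating_renewal()].
#' @param profile A [drug_profile()]; `fs` must be at least twice
#'   `burst_band_hi`.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param envelope Burst envelope model, `"stabilized"` or `"gaussian"`.
#' @return An [recording()] spanning `[0, max(events$end))`.
#' @export
render_waveform <- function(events, profile, fs, seed = NULL,
                            envelope = c("stabilized", "gaussian")) {
  stopifnot(inherits(profile, "drug_profile"))
  envelope <- match.arg(envelope)
  if (fs < 2 * profile$burst_band_hi)
    stop_input("fs = %g Hz violates Nyquist for burst band up to %g Hz",
               fs, profile$burst_band_hi)
  if (nrow(events) == 0L)
    return(recording(numeric(0), fs, label = profile$name))
  total <- max(events$end)
  n <- round(total * fs)
  with_seed(seed, {
    nyq <- fs / 2
    bb <- signal::butter(4, c(profile$burst_band_lo, profile$burst_band_hi) / nyq,
                         type = "pass")
    sb <- signal::butter(4, min(profile$supp_band_hi, 0.9 * nyq) / nyq,
                         type = "low")
    xb <- signal::filtfilt(bb, rnorm(n))
    if (envelope == "stabilized")
      xb <- xb / pmax(hilbert_envelope(xb), 1e-12)
    xs <- signal::filtfilt(sb, rnorm(n))
    xb <- xb / stats::sd(xb) * profile$burst_amp
    xs <- xs / stats::sd(xs) * profile$supp_amp
    m <- burst_mask(events, fs, n, profile$taper_time)
    recording(m * xb + (1 - m) * xs, fs, label = profile$name)
  })
}

# magnitude of the analytic signal, via the frequency-domain Hilbert
# transform
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# Per-sample mask: 1 inside bursts, 0 inside suppressions, raised-cosine
# ramps of length taper_time centered on each transition.
burst_mask <- function(events, fs, n, taper_time) {
  t <- (seq_len(n) - 0.5) / fs
  lab <- event_labels_at(events, t)
  m <- as.numeric(lab == "burst")
  if (taper_time <= 0 || nrow(events) < 2L) return(m)
  half <- taper_time / 2
  for (k in 2:nrow(events)) {
    tt <- events$start[k]
    idx <- which(t >= tt - half & t < tt + half)
    if (!length(idx)) next
    phase <- (t[idx] - (tt - half)) / taper_time  # 0 -> 1 across the taper
    ramp <- (1 - cos(pi * phase)) / 2
    m[idx] <- if (events$label[k] == "burst") ramp else 1 - ramp
  }
  m
}

# Label of the event covering each time (half-open [start, end)).
event_labels_at <- function(events, t) {
  idx <- findInterval(t, events$start)
  idx[idx < 1L] <- 1L
  events$label[idx]
}

#' Bernoulli binary series with known probabilities
#'
#' Draws independent Bernoulli indicators (1 = suppression) from a
#' per-step probability sequence. This is the direct test input for the
#' BSP estimator.
#'
#' @param p_true Vector of probabilities in \[0, 1\].
#' @param delta Sampling interval in seconds (> 0).
#' @param seed Integer seed.
#' @return A [binary_series()].
#' @export
generate_binary_series <- function(p_true, delta = 0.02, seed = NULL) {
  if (!is.numeric(p_true) || any(!is.finite(p_true)) ||
      any(p_true < 0 | p_true > 1))
    stop_input("'p_true' must be probabilities in [0, 1]")
  with_seed(seed, binary_series(rbinom(length(p_true), 1L, p_true), delta))
}

#' Generate a synthetic burst-suppression recording with ground truth
#'
#' Composes [sample_alternating_renewal()] and [render_waveform()] and
#' assembles the ground truth: per-sample labels, the event list, and the
#' per-sample true suppression probability. By default the target
#' suppression fraction drifts from 0.4 to 0.7 across the recording,
#' emulating deepening anesthesia so that events span the analysis range
#' of BSP levels; set `depth_range = NULL` for a stationary process at
#' the profile's own long-run fraction `E[S] / (E[S] + E[B])`.
#'
#' @param profile A [drug_profile()].
#' @param total_duration Recording length in seconds.
#' @param fs Sampling rate in Hz (default 500).
#' @param seed Integer seed; the full output is reproducible from
#'   `(profile, total_duration, fs, seed)`.
#' @param first First event label, `"burst"` (default) or `"random"`.
#' @param envelope Burst envelope model; see [render_waveform()].
#' @param depth_range Drift of the target suppression fraction; see
#'   [sample_alternating_renewal()].
#' @return An object of class `synthetic_recording`: list with elements
#'   `recording` ([recording()]), `truth` (list `labels`, `events`,
#'   `p_true`), `profile`, `seed`.
#' @export
generate_recording <- function(profile, total_duration, fs = 500, seed = NULL,
                               first = c("burst", "random"),
                               envelope = c("stabilized", "gaussian"),
                               depth_range = c(0.4, 0.7)) {
  first <- match.arg(first)
  envelope <- match.arg(envelope)
  events <- sample_alternating_renewal(profile, total_duration, seed, first,
                                       depth_range)
  wf_seed <- if (is.null(seed)) NULL else as.integer(seed) + 1013904L
  rec <- render_waveform(events, profile, fs, wf_seed, envelope)
  t <- (seq_along(rec$samples) - 0.5) / fs
  labels <- event_labels_at(events, t)
  p_true <- if (is.null(depth_range)) {
    rep(profile_means(profile)$supp_fraction, length(labels))
  } else {
    depth_fraction(t, total_duration, depth_range)
  }
  structure(list(recording = rec,
                 truth = list(labels = labels, events = events,
                              p_true = p_true),
                 profile = profile,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording '%s': %.0f s @ %g Hz, %d events, seed %s>\n",
              x$profile$name, duration(x$recording), x$recording$fs,
              nrow(x$truth$events), x$seed))
  invisible(x)
}
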