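#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), giving zero phase distortion and the acquisition
#' band used for rodent burst-suppression EEG (0.3--50 Hz by default).
#'
#' @param rec An [recording()] object.
#' @param lo,hi Band edges in Hz; `0 <= lo < hi < fs/2`.
#' @param order Butterworth order per pass (default 4).
#' @return A filtered `eeg_recording` of the same length and rate.
#' @export
bandpass_filter <- function(rec, lo = 0.3, hi = 50, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!is.numeric(lo) || !is.numeric(hi) || lo < 0 || lo >= hi || hi >= nyq)
    stop_input("band [%g, %g] Hz must satisfy 0 <= lo < hi < fs/2 = %g",
               lo, hi, nyq)
  if (lo == 0) {
    flt <- signal::butter(order, hi / nyq, type = "low")
  } else {
    flt <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  }
  out <- signal::filtfilt(flt, rec$samples)
  recording(out, rec$fs, rec$start_time, rec$label)
}

#' Resample a recording
#'
#' Anti-alias filters then decimates to a new rate. The anti-alias corner
#' sits at `aa_frac * fs_out` (default 0.45, i.e. 22.5 Hz when resampling
#' to 50 Hz), so content up to ~0.45 of the output rate survives intact.
#'
#' @param rec An [recording()] object.
#' @param fs_out Output sampling rate in Hz; must be `<= fs`.
#' @param aa_frac Anti-alias low-pass corner as a fraction of `fs_out`.
#' @return A resampled `eeg_recording` with
#'   `length == round(n * fs_out / fs)`.
#' @export
resample_recording <- function(rec, fs_out = 50, aa_frac = 0.45) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(fs_out) || length(fs_out) != 1L || fs_out <= 0)
    stop_input("'fs_out' must be a single positive number")
  if (fs_out > rec$fs)
    stop_input("fs_out = %g exceeds the input rate %g Hz", fs_out, rec$fs)
  if (fs_out == rec$fs) return(rec)
  x <- rec$samples
  corner <- aa_frac * fs_out
  if (corner < rec$fs / 2) {
    flt <- signal::butter(8, corner / (rec$fs / 2), type = "low")
    x <- signal::filtfilt(flt, x)
  }
  n_out <- round(length(x) * fs_out / rec$fs)
  # sample the anti-aliased trace at the output grid (linear interpolation
  # between input samples; exact when fs/fs_out is an integer)
  t_in <- (seq_along(x) - 1L) / rec$fs
  t_out <- (seq_len(n_out) - 1L) / fs_out
  out <- approx(t_in, x, xout = pmin(t_out, max(t_in)))$y
  recording(out, fs_out, rec$start_time, rec$label)
}

#' Remove a linear trend
#'
#' Subtracts the least-squares straight line, leaving a zero-mean,
#' trend-free trace.
#'
#' @param rec An [recording()] object with at least 2 samples.
#' @return A detrended `eeg_recording`.
#' @export
detrend_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- length(rec$samples)
  if (n < 2L) stop_input("detrending needs at least 2 samples")
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), rec$samples)
  recording(unname(fit$residuals), rec$fs, rec$start_time, rec$label)
}

#' Gaussian smoothing
#'
#' Convolves with a unit-area Gaussian kernel of standard deviation
#' `sigma` seconds, truncated at +/- 4 sigma, with reflective boundary
#' handling. Used to condition the EEG before the nonlinear energy
#' operator.
#'
#' @param rec An [recording()] object.
#' @param sigma Kernel standard deviation in seconds (> 0); default 0.1.
#' @return A smoothed `eeg_recording` of the same length.
#' @export
gaussian_smooth <- function(rec, sigma = 0.1) {
  stopifnot(inherits(rec, "eeg_recording"))
  recording(gaussian_smooth_vec(rec$samples, sigma, rec$fs),
            rec$fs, rec$start_time, rec$label)
}

gaussian_smooth_vec <- function(x, sigma, fs) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop_input("'sigma' must be a single positive number (seconds)")
  half <- max(1L, ceiling(4 * sigma * fs))
  k <- exp(-((-half:half) / fs)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(x)
  # reflect at both ends so the kernel always sees real data
  pad <- c(x[pmin(half, n):1], x, x[n:max(1L, n - half + 1L)])
  out <- stats::filter(pad, k, method = "convolution", sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Standard preprocessing chain
#'
#' Applies, in order: zero-phase band-pass, resampling, linear
#' detrending, and (optionally) Gaussian smoothing. This mirrors the
#' acquisition-chain conditioning used for rodent burst-suppression EEG:
#' a 0.3--50 Hz band, downsampling to 50 Hz, detrending, then smoothing
#' ahead of energy computation. Set `smooth_sigma = NULL` to obtain the
#' conditioned (unsmoothed) trace used for feature extraction and
#' spectral analysis.
#'
#' @param rec An [recording()] object.
#' @param lo,hi Band edges in Hz.
#' @param fs_out Output rate in Hz (`NULL` to skip resampling).
#' @param smooth_sigma Gaussian kernel SD in seconds, or `NULL` to skip.
#' @return A preprocessed `eeg_recording`.
#' @export
preprocess <- function(rec, lo = 0.3, hi = 50, fs_out = 50,
                       smooth_sigma = 0.1) {
  out <- bandpass_filter(rec, lo, hi)
  if (!is.null(fs_out)) out <- resample_recording(out, fs_out)
  out <- detrend_recording(out)
  if (!is.null(smooth_sigma)) out <- gaussian_smooth(out, smooth_sigma)
  out
}
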