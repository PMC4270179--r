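#' Drug-specific burst-suppression profile
#'
#' A profile parameterizes the synthetic burst-suppression generator:
#' gamma-distributed burst and suppression durations, target RMS
#' amplitudes for the two states, the oscillatory pass band of burst
#' content, and the transition taper length. Durations are gamma because
#' they are positive and right-skewed; only medians are reported for real
#' recordings, so the family is a modeling choice.
#'
#' @param name Profile name.
#' @param burst_dur_shape,burst_dur_scale Gamma shape/scale for burst
#'   durations (s).
#' @param supp_dur_shape,supp_dur_scale Gamma shape/scale for suppression
#'   durations (s).
#' @param burst_amp Target burst RMS amplitude (uV).
#' @param supp_amp Target suppression RMS amplitude (uV); must be smaller
#'   than `burst_amp`.
#' @param burst_band_lo,burst_band_hi Pass band of burst oscillatory
#'   content (Hz); the default 2--10 Hz reflects the delta/theta
#'   dominance of anesthetic bursts.
#' @param supp_band_hi Low-pass corner of the suppression background
#'   (Hz); suppressions are residual low-frequency activity, not silence.
#' @param taper_time Raised-cosine transition taper length (s).
#' @return An object of class `drug_profile`.
#' @seealso [sevoflurane_profile()], [propofol_profile()],
#'   [generate_recording()]
#' @export
drug_profile <- function(name,
                         burst_dur_shape, burst_dur_scale,
                         supp_dur_shape, supp_dur_scale,
                         burst_amp, supp_amp,
                         burst_band_lo = 2, burst_band_hi = 10,
                         supp_band_hi = 2.5,
                         taper_time = 0.05) {
  num <- c(burst_dur_shape = burst_dur_shape, burst_dur_scale = burst_dur_scale,
           supp_dur_shape = supp_dur_shape, supp_dur_scale = supp_dur_scale,
           burst_amp = burst_amp, supp_amp = supp_amp,
           burst_band_lo = burst_band_lo, burst_band_hi = burst_band_hi,
           supp_band_hi = supp_band_hi, taper_time = taper_time)
  if (any(!is.finite(num)) || any(num[names(num) != "taper_time"] <= 0))
    stop_input("all profile duration/amplitude/band parameters must be strictly positive")
  if (taper_time < 0) stop_input("'taper_time' must be >= 0")
  if (burst_band_lo >= burst_band_hi)
    stop_input("'burst_band_lo' must be below 'burst_band_hi'")
  if (burst_amp <= supp_amp)
    stop_input("'burst_amp' must exceed 'supp_amp'")
  structure(c(list(name = as.character(name)), as.list(num)),
            class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat(sprintf("<drug_profile '%s'>\n", x$name))
  cat(sprintf("  burst durations: gamma(shape=%g, scale=%g), mean %.2f s\n",
              x$burst_dur_shape, x$burst_dur_scale,
              x$burst_dur_shape * x$burst_dur_scale))
  cat(sprintf("  supp. durations: gamma(shape=%g, scale=%g), mean %.2f s\n",
              x$supp_dur_shape, x$supp_dur_scale,
              x$supp_dur_shape * x$supp_dur_scale))
  cat(sprintf("  RMS amplitudes: burst %g uV, suppression %g uV\n",
              x$burst_amp, x$supp_amp))
  cat(sprintf("  burst band: %g-%g Hz; taper %g s\n",
              x$burst_band_lo, x$burst_band_hi, x$taper_time))
  invisible(x)
}

# mean sojourn times and implied long-run suppression fraction
profile_means <- function(profile) {
  eb <- profile$burst_dur_shape * profile$burst_dur_scale
  es <- profile$supp_dur_shape * profile$supp_dur_scale
  list(burst = eb, supp = es, supp_fraction = es / (es + eb))
}

#' Default sevoflurane-like profile
#'
#' Long, high-amplitude bursts and suppressions: mean burst 1.7 s, mean
#' suppression 2.5 s (long-run suppression fraction ~0.6), burst RMS
#' 190 uV and suppression RMS 41 uV. Calibrated so that, at a mid-level of
#' suppression, segmented synthetic events reproduce the reported ordering
#' and rough magnitudes of sevoflurane vs. propofol burst-suppression
#' features (e.g. suppression peak-to-peak near 136 uV).
#'
#' @return A `drug_profile`.
#' @export
sevoflurane_profile <- function() {
  drug_profile("sevoflurane-like",
               burst_dur_shape = 2, burst_dur_scale = 0.85,
               supp_dur_shape = 2, supp_dur_scale = 1.25,
               burst_amp = 190, supp_amp = 41)
}

#' Default propofol-like profile
#'
#' Short, low-amplitude bursts and suppressions: mean burst 0.45 s, mean
#' suppression 0.7 s, burst RMS 72 uV and suppression RMS 23 uV
#' (suppression peak-to-peak near 52 uV, burst peak-to-peak near 196 uV
#' after segmentation). The burst band sits higher (3--12 Hz) than the
#' sevoflurane-like profile's, reflecting the alpha/spindle-range
#' content of propofol bursts.
#'
#' @return A `drug_profile`.
#' @export
propofol_profile <- function() {
  drug_profile("propofol-like",
               burst_dur_shape = 2, burst_dur_scale = 0.225,
               supp_dur_shape = 2, supp_dur_scale = 0.35,
               burst_amp = 72, supp_amp = 23,
               burst_band_lo = 3, burst_band_hi = 12)
}
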