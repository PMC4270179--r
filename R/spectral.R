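#' Number of multitaper tapers
#'
#' For a window of length `T` seconds and half-bandwidth `W` Hz, the
#' standard taper count is `K = floor(2 T W) - 1` (e.g. a 2 s window with
#' 1 Hz half-bandwidth gives 3 tapers).
#'
#' @param T Window length in seconds.
#' @param W Half-bandwidth in Hz; `T * W >= 1` required.
#' @return Integer taper count.
#' @export
taper_count <- function(T, W) {
  if (T * W < 1) stop_input("time-bandwidth product T*W = %g must be >= 1", T * W)
  as.integer(floor(2 * T * W) - 1)
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, as the top eigenvectors of the standard symmetric
#' tridiagonal commuting matrix. Tapers are unit-energy; signs follow the
#' usual convention (symmetric tapers have positive mean, antisymmetric
#' tapers start with a positive lobe).
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (`n * W / fs`).
#' @param k Number of tapers.
#' @return `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  if (k < 1 || k > n) stop_input("'k' must be between 1 and n")
  if (nw <= 0 || nw >= n / 2) stop_input("'nw' must be in (0, n/2)")
  w <- nw / n
  i <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(i + 1, i + 1)] <- diag_v
  A[cbind(1:(n - 1), 2:n)] <- off_v
  A[cbind(2:n, 1:(n - 1))] <- off_v
  eg <- eigen(A, symmetric = TRUE)
  H <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    h <- H[, j]
    h <- h / sqrt(sum(h^2))
    if (j %% 2L == 1L) {            # symmetric order: positive mean
      if (sum(h) < 0) h <- -h
    } else {                        # antisymmetric order: positive start
      lead <- h[which(abs(h) > max(abs(h)) * 1e-6)[1]]
      if (lead < 0) h <- -h
    }
    H[, j] <- h
  }
  H
}

#' Multitaper spectrogram
#'
#' Sliding-window multitaper power spectral density: per window, the
#' eigenspectra of `K = taper_count(window, half_bandwidth)` Slepian
#' tapers (time-bandwidth product `window * half_bandwidth`) are averaged
#' with equal weights. Defaults match burst-suppression practice: 2 s
#' windows stepped by 50 ms with 1 Hz half-bandwidth (3 tapers).
#'
#' @param rec An [recording()] at least one window long.
#' @param window Window length in seconds.
#' @param step Hop between window starts in seconds (> 0).
#' @param half_bandwidth Spectral half-bandwidth W in Hz.
#' @param db Return power in dB re 1 uV^2/Hz (default) or linear.
#' @return An object of class `spectrogram`: list with `times` (window
#'   centers, s), `freqs` (Hz, 0 to fs/2), `power` (time x frequency
#'   matrix), `fs`, `db`.
#' @export
multitaper_spectrogram <- function(rec, window = 2, step = 0.05,
                                   half_bandwidth = 1, db = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (step <= 0) stop_input("'step' must be > 0")
  n <- length(rec$samples)
  nwin <- round(window * rec$fs)
  if (nwin > n) stop_input("window (%g s) exceeds the recording length", window)
  k <- taper_count(window, half_bandwidth)
  H <- dpss_tapers(nwin, window * half_bandwidth, k)
  hop <- step * rec$fs
  n_frames <- floor((n - nwin) / hop) + 1
  nfreq <- nwin %/% 2 + 1
  freqs <- (0:(nfreq - 1)) * rec$fs / nwin
  P <- matrix(0, n_frames, nfreq)
  times <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    i0 <- floor((f - 1) * hop) + 1
    seg <- rec$samples[i0:(i0 + nwin - 1)]
    S <- 0
    for (j in seq_len(k)) {
      Y <- fft(seg * H[, j])
      S <- S + Mod(Y[seq_len(nfreq)])^2 / rec$fs
    }
    S <- S / k
    # fold to one-sided density
    if (nfreq > 2) {
      inner <- 2:(nfreq - 1)
      if (nwin %% 2 == 0) S[inner] <- 2 * S[inner]
      else S[2:nfreq] <- 2 * S[2:nfreq]
    }
    P[f, ] <- S
    times[f] <- rec$start_time + (i0 - 1 + (nwin - 1) / 2) / rec$fs
  }
  if (db) P <- 10 * log10(pmax(P, .Machine$double.xmin))
  structure(list(times = times, freqs = freqs, power = P,
                 fs = rec$fs, db = db, window = window, step = step,
                 half_bandwidth = half_bandwidth, n_tapers = k),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d frames x %d frequencies (0-%g Hz), %d tapers, %s>\n",
              length(x$times), length(x$freqs), max(x$freqs), x$n_tapers,
              if (x$db) "dB" else "linear"))
  invisible(x)
}

#' @export
plot.spectrogram <- function(x, ..., fmax = NULL, floor_db = -40) {
  P <- x$power
  if (!x$db) P <- 10 * log10(pmax(P, .Machine$double.xmin))
  P <- pmax(P, max(P) + floor_db)   # display floor relative to the maximum
  sel <- if (is.null(fmax)) seq_along(x$freqs) else which(x$freqs <= fmax)
  image(x$times, x$freqs[sel], P[, sel, drop = FALSE],
        xlab = "time (s)", ylab = "frequency (Hz)",
        col = hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Write a spectrogram as a text matrix
#'
#' Tab-separated matrix with a frequency header row and window-center
#' times in the first column.
#'
#' @param spec A [multitaper_spectrogram()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrogram <- function(spec, path) {
  stopifnot(inherits(spec, "spectrogram"))
  m <- cbind(time_s = spec$times, spec$power)
  colnames(m) <- c("time_s", sprintf("f_%g", spec$freqs))
  write.table(format(m, trim = TRUE, digits = 8), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
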