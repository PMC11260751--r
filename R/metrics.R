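#' Peak-to-peak amplitude within a time window
#'
#' `max - min` of the samples inside the window. The default window (8-18 ms)
#' is the postauricular-muscle artifact search window.
#'
#' @param w A [waveform].
#' @param window Length-2 `c(from, to)` in ms.
#' @return Peak-to-peak amplitude in the waveform's units (non-negative).
#' @export
peak_to_peak <- function(w, window = c(8, 18)) {
  idx <- window_indices(w, window)
  x <- w$samples[idx]
  max(x) - min(x)
}

#' Root-mean-square amplitude within a time window
#'
#' The FFR magnitude measure. The default window (10-110 ms) covers the
#' 100 ms stimulus plus approximately 10 ms of neural transmission delay.
#'
#' @param w A [waveform].
#' @param window Length-2 `c(from, to)` in ms.
#' @return RMS amplitude in the waveform's units.
#' @export
rms_amplitude <- function(w, window = c(10, 110)) {
  idx <- window_indices(w, window)
  sqrt(mean(w$samples[idx]^2))
}

#' Latency of the maximal positive deflection
#'
#' Returns the time (ms) of the largest positive sample within a search
#' window, the conventional wave-peak latency definition. The FFR onset
#' latency uses a 6-12 ms search window and the PAM artifact an 8-18 ms
#' window.
#'
#' @param w A [waveform].
#' @param search Length-2 `c(from, to)` search window in ms.
#' @param flat_tol Waveforms whose within-window range is below `flat_tol`
#'   are treated as flat and return `NA` with a warning (no identifiable
#'   peak).
#' @return Latency in ms, or `NA_real_` for a flat window.
#' @export
onset_latency <- function(w, search = c(6, 12), flat_tol = 1e-12) {
  idx <- window_indices(w, search)
  x <- w$samples[idx]
  if (diff(range(x)) < flat_tol) {
    warning("waveform is flat within the search window; latency undefined")
    return(NA_real_)
  }
  time_axis_ms(w)[idx[which.max(x)]]
}

#' Amplitude spectrum value at a target frequency
#'
#' Magnitude of the discrete spectrum of an analysis window at the bin
#' nearest `freq`, amplitude-normalized so that a pure sinusoid of amplitude
#' A returns approximately A. The window is rectangular-tapered (appropriate
#' for periodic steady-state responses) and zero-padded to at least 1 Hz bin
#' resolution.
#'
#' @param w A [waveform].
#' @param freq Target frequency in Hz; must lie below `fs/2`.
#' @param window Analysis window `c(from, to)` in ms (default the FFR
#'   steady-state window, 10-110 ms).
#' @param resolution_hz Maximum bin spacing after zero-padding (default 1 Hz).
#' @return Amplitude at the nearest bin, same units as the waveform.
#' @export
spectrum_amplitude <- function(w, freq, window = c(10, 110),
                               resolution_hz = 1) {
  if (freq >= w$fs / 2) {
    stop(sprintf("freq %g Hz is at or above the Nyquist frequency %g Hz",
                 freq, w$fs / 2))
  }
  idx <- window_indices(w, window)
  x <- w$samples[idx]
  n <- length(x)
  if (n < 2 * w$fs / max(freq, 1e-12)) {
    stop("analysis window must span at least two cycles of the target frequency")
  }
  nfft <- max(n, ceiling(w$fs / resolution_hz))
  spec <- stats::fft(c(x, numeric(nfft - n)))
  freqs <- (seq_len(nfft) - 1) * w$fs / nfft
  half <- seq_len(floor(nfft / 2) + 1)
  bin <- half[which.min(abs(freqs[half] - freq))]
  # one-sided amplitude normalization: sinusoid of amplitude A -> A
  2 * Mod(spec[bin]) / n
}

#' Maximal normalized cross-correlation over a lag window
#'
#' Slides `b` against `a` over lags |tau| <= `max_lag_ms` and computes the
#' Pearson correlation of the overlapping segments at each lag, returning the
#' (signed) maximum and its lag. Positive lags mean `b` is delayed relative
#' to `a`.
#'
#' @param a,b [waveform]s with equal sampling rates.
#' @param max_lag_ms Lag search half-width in ms (default 20).
#' @return An object of class `xcorr_result`: list with `r_max`, `lag_ms`,
#'   and the per-lag correlation profile (`lags_ms`, `r`).
#' @examples
#' w <- waveform(sin(2 * pi * 100 * seq(0, 0.1, 5e-5)), 20000)
#' xcorr_max(w, w)$r_max   # 1 at lag 0
#' @export
xcorr_max <- function(a, b, max_lag_ms = 20) {
  stopifnot(inherits(a, "waveform"), inherits(b, "waveform"))
  if (abs(a$fs - b$fs) > 1e-9) stop("waveforms have mismatched sampling rates")
  if (stats::sd(a$samples) == 0 || stats::sd(b$samples) == 0) {
    stop("cross-correlation undefined for zero-variance input")
  }
  max_lag <- floor(max_lag_ms * a$fs / 1000)
  xa <- a$samples; xb <- b$samples
  lags <- seq.int(-max_lag, max_lag)
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      sb <- xb[(1 + k):length(xb)]
      sa <- xa[1:length(sb)]
    } else {
      sa <- xa[(1 - k):length(xa)]
      sb <- xb[1:length(sa)]
    }
    n <- min(length(sa), length(sb))
    if (n < 3) return(NA_real_)
    sa <- sa[1:n]; sb <- sb[1:n]
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) return(NA_real_)
    stats::cor(sa, sb)
  }, numeric(1))
  ok <- which(!is.na(r))
  best <- ok[which.max(r[ok])]
  structure(
    list(r_max = r[best], lag_ms = lags[best] * 1000 / a$fs,
         lags_ms = lags * 1000 / a$fs, r = r),
    class = "xcorr_result"
  )
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat(sprintf("<xcorr_result> r_max = %.4f at lag %.3f ms\n", x$r_max, x$lag_ms))
  invisible(x)
}

# amplitudes at several harmonics of f0 from a single zero-padded FFT of the
# analysis window (same normalization as spectrum_amplitude)
harmonic_amplitudes <- function(w, f0, harmonics = c(1, 2, 3),
                                window = c(10, 110), resolution_hz = 1) {
  idx <- window_indices(w, window)
  x <- w$samples[idx]
  n <- length(x)
  nfft <- max(n, ceiling(w$fs / resolution_hz))
  spec <- stats::fft(c(x, numeric(nfft - n)))
  freqs <- (seq_len(nfft) - 1) * w$fs / nfft
  half <- seq_len(floor(nfft / 2) + 1)
  vapply(harmonics * f0, function(fr) {
    bin <- half[which.min(abs(freqs[half] - fr))]
    2 * Mod(spec[bin]) / n
  }, numeric(1))
}
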