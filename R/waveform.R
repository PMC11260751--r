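#' Uniformly sampled waveform
#'
#' The basic carrier for all signals in the package: stimuli (unitless),
#' single-channel evoked potentials and isolated artifacts (microvolts).
#' Samples are uniformly spaced at rate `fs`; `t0_ms` is the time of the
#' first sample relative to stimulus onset.
#'
#' @param samples Numeric vector of sample values (microvolts, or unitless
#'   for stimuli). Must be finite.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param t0_ms Time of the first sample in milliseconds (default 0).
#'
#' @return An object of class `waveform`: a list with elements `samples`,
#'   `fs` and `t0_ms`.
#' @examples
#' w <- waveform(sin(2 * pi * 100 * seq(0, 0.1, by = 5e-5)), fs = 20000)
#' duration_ms(w)
#' @export
waveform <- function(samples, fs, t0_ms = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("waveform needs at least one sample")
  if (!all(is.finite(samples))) stop("waveform samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a positive finite scalar (Hz)")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), t0_ms = as.numeric(t0_ms)),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform> %d samples @ %g Hz, t = [%.3f, %.3f] ms, range [%.4g, %.4g]\n",
    length(x$samples), x$fs, x$t0_ms, end_time_ms(x),
    min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' @export
plot.waveform <- function(x, ..., xlab = "Time (ms)", ylab = "Amplitude",
                          type = "l") {
  graphics::plot(time_axis_ms(x), x$samples, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Time axis of a waveform in milliseconds
#' @param w A [waveform].
#' @return Numeric vector of sample times (ms).
#' @export
time_axis_ms <- function(w) {
  stopifnot(inherits(w, "waveform"))
  w$t0_ms + (seq_along(w$samples) - 1) * 1000 / w$fs
}

#' Duration of a waveform in milliseconds
#' @param w A [waveform].
#' @return Duration spanned by the samples (ms).
#' @export
duration_ms <- function(w) (length(w$samples)) * 1000 / w$fs

end_time_ms <- function(w) w$t0_ms + (length(w$samples) - 1) * 1000 / w$fs

#' Sample indices falling inside a time window
#'
#' @param w A [waveform].
#' @param window Length-2 numeric vector `c(from, to)` in ms (inclusive).
#' @return Integer vector of indices into `w$samples`.
#' @keywords internal
window_indices <- function(w, window) {
  stopifnot(inherits(w, "waveform"), length(window) == 2L)
  if (window[2] < window[1]) stop("window must satisfy from <= to")
  t <- time_axis_ms(w)
  idx <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
  if (length(idx) == 0L) {
    stop(sprintf("window [%g, %g] ms contains no samples (waveform spans [%g, %g] ms)",
                 window[1], window[2], w$t0_ms, end_time_ms(w)))
  }
  idx
}

check_same_grid <- function(a, b) {
  stopifnot(inherits(a, "waveform"), inherits(b, "waveform"))
  if (abs(a$fs - b$fs) > 1e-9) {
    stop("waveforms have mismatched sampling rates")
  }
  if (abs(a$t0_ms - b$t0_ms) > 1e-9 || length(a$samples) != length(b$samples)) {
    stop("waveforms have mismatched time grids")
  }
  invisible(TRUE)
}
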