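#' Stimulus specification
#'
#' Describes the click / periodic click-train stimuli used to elicit ABRs and
#' FFRs. The train is a periodic series of impulses with period `T = 1/f0`
#' convolved with a single click; each pulse of the train is an identical
#' click. Presentation level and repetition rate are carried as metadata only
#' (no acoustic calibration is performed; stimulus amplitude is
#' unit-normalized).
#'
#' @param f0 Fundamental frequency of the pulse train in Hz (100 or 200 in
#'   the reference recordings; any positive value is accepted).
#' @param duration_ms Train duration `d` in ms (default 100).
#' @param click_width_us Click (pulse) width in microseconds (default 100).
#' @param polarity `"rarefaction"` (negative-going, the default) or
#'   `"condensation"` (sign-flipped).
#' @param fs Sampling rate in Hz (default 20000). Must be at least twice the
#'   3,000 Hz recording band edge.
#' @param level_dbspl Presentation level metadata, dB SPL (default 80).
#' @param rep_rate Presentation repetition-rate metadata, per second
#'   (default 9.09).
#'
#' @return An object of class `stim_spec`.
#' @examples
#' spec <- stim_spec(f0 = 100)
#' train <- make_click_train(spec)
#' @export
stim_spec <- function(f0 = 100, duration_ms = 100, click_width_us = 100,
                      polarity = c("rarefaction", "condensation"),
                      fs = 20000, level_dbspl = 80, rep_rate = 9.09) {
  polarity <- match.arg(polarity)
  if (!is.numeric(f0) || f0 <= 0) stop("f0 must be positive (Hz)")
  if (fs < 2 * 3000) stop("fs must be at least 6000 Hz to cover the 50-3000 Hz recording passband")
  if (duration_ms <= 0) stop("duration_ms must be positive")
  if (1000 / f0 < 1000 / fs) stop("stimulus period 1/f0 must span at least one sample")
  structure(
    list(f0 = f0, duration_ms = duration_ms, click_width_us = click_width_us,
         polarity = polarity, fs = fs, level_dbspl = level_dbspl,
         rep_rate = rep_rate),
    class = "stim_spec"
  )
}

#' @export
print.stim_spec <- function(x, ...) {
  cat(sprintf(
    "<stim_spec> f0 = %g Hz, d = %g ms, click = %g us (%s), fs = %g Hz, %g dB SPL @ %g/s\n",
    x$f0, x$duration_ms, x$click_width_us, x$polarity, x$fs, x$level_dbspl,
    x$rep_rate
  ))
  invisible(x)
}

#' Construct a single click
#'
#' A rectangular pulse of width `click_width_us`. Rarefaction polarity is
#' rendered as a negative-going deflection (unit amplitude); condensation is
#' the sign-flipped copy.
#'
#' @param spec A [stim_spec].
#' @return A [waveform] containing only the nonzero click samples.
#' @examples
#' make_click(stim_spec())          # 2 samples of -1 at fs = 20 kHz
#' @export
make_click <- function(spec) {
  stopifnot(inherits(spec, "stim_spec"))
  sample_period_us <- 1e6 / spec$fs
  n <- floor(spec$click_width_us / sample_period_us)
  if (n < 1L) {
    stop(sprintf(
      "click width %g us is below one sample period; minimum representable width at fs = %g Hz is %g us",
      spec$click_width_us, spec$fs, sample_period_us
    ))
  }
  amp <- if (spec$polarity == "rarefaction") -1 else 1
  waveform(rep(amp, n), fs = spec$fs, t0_ms = 0)
}

#' Construct a periodic impulse train
#'
#' Unit impulses at t = 0, T, 2T, ... for t < d, with T = 1/f0. The first
#' pulse is placed at t = 0 so derived responses align with the recording
#' epoch origin. The impulse count is exactly `ceiling(d * f0)`.
#'
#' @param spec A [stim_spec].
#' @return A [waveform] of duration `duration_ms` containing the impulses.
#' @examples
#' sum(make_pulse_train(stim_spec(f0 = 100))$samples != 0)  # 10 impulses
#' @export
make_pulse_train <- function(spec) {
  stopifnot(inherits(spec, "stim_spec"))
  T_ms <- 1000 / spec$f0
  if (spec$duration_ms < T_ms) {
    stop(sprintf("train duration %g ms is shorter than one period (%g ms)",
                 spec$duration_ms, T_ms))
  }
  n <- round(spec$duration_ms * spec$fs / 1000)
  samples <- numeric(n)
  k <- ceiling(spec$duration_ms * spec$f0 / 1000)  # pulses strictly before d
  t_pulse_ms <- (seq_len(k) - 1) * T_ms
  idx <- round(t_pulse_ms * spec$fs / 1000) + 1L
  idx <- idx[idx <= n]
  samples[idx] <- 1
  waveform(samples, fs = spec$fs, t0_ms = 0)
}

#' Construct a periodic click train
#'
#' The convolution of the impulse train with a single click: every pulse of
#' the train is an identical click (same width, amplitude and polarity).
#'
#' @param spec A [stim_spec].
#' @return A [waveform]; length is the full linear-convolution support.
#' @examples
#' train <- make_click_train(stim_spec(f0 = 200))
#' @export
make_click_train <- function(spec) {
  pulses <- make_pulse_train(spec)
  click <- make_click(spec)
  waveform(lin_conv(pulses$samples, click$samples), fs = spec$fs, t0_ms = 0)
}

# linear (acyclic) convolution; exact superposition sum when either input is
# sparse or short (the usual case: impulse trains, clicks), FFT otherwise
lin_conv <- function(a, b) {
  na <- length(a); nb <- length(b)
  nza <- sum(a != 0); nzb <- sum(b != 0)
  if (min(nza, nzb) <= 128L) {
    if (nza <= nzb) { short <- a; long <- b } else { short <- b; long <- a }
    out <- numeric(na + nb - 1L)
    nl <- length(long)
    for (i in which(short != 0)) {
      out[i:(i + nl - 1L)] <- out[i:(i + nl - 1L)] + short[i] * long
    }
    out
  } else {
    stats::convolve(a, rev(b), type = "open")
  }
}
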