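# Deterministic waveform templates used by the synthetic cohort generator.
#
# All planted amplitudes are defined AFTER the standard 50-3000 Hz zero-phase
# band-pass (the reference recordings are hardware-filtered online, so every
# published amplitude is a post-filter measurement). Template constructors
# therefore normalize against the band-passed version of their shape.

GAZE_ANGLES <- c(-70, -35, 0, 35, 70)

# fixed scattered harmonic phases (radians) for the sustained neural FFR
# template; chosen once so the neurogenic component does not accidentally
# align with the periodized PAM wavelet
NEURAL_PHASES <- c(0.40, 2.10, 4.60, 1.20, 5.30, 3.10, 0.70, 2.90,
                   4.70, 1.90, 5.90, 3.70)

#' Gaze-dependent PAM gain
#'
#' Fraction of the maximal postauricular-muscle contraction elicited at gaze
#' angle `theta`:
#' `g(theta) = gaze_floor + (1 - gaze_floor) * (|theta|/70)^gaze_exponent`.
#' Symmetric in theta, equal to 1 at +/-70 degrees and to `gaze_floor` at the
#' midline.
#'
#' @param theta Gaze angle in degrees, within \[-70, 70\].
#' @param structure An [effect_structure] supplying `gaze_floor` and
#'   `gaze_exponent`.
#' @param exponent Optional subject-specific exponent overriding the
#'   structure-level `gaze_exponent`.
#' @return Gain fraction in (0, 1\].
#' @export
gaze_gain <- function(theta, structure = effect_structure(),
                      exponent = NULL) {
  if (any(abs(theta) > 70)) stop("gaze angle must lie within [-70, 70] degrees")
  p <- if (!is.null(exponent) && !is.na(exponent)) exponent else structure$gaze_exponent
  structure$gaze_floor +
    (1 - structure$gaze_floor) * (abs(theta) / 70)^p
}

#' Canonical click-ABR template for one subject
#'
#' Sum of three positive Gaussian-windowed deflections at the subject's wave
#' I/III/V latencies (defaults 1.5 / 3.5 / 5.5 ms), scaled by the subject's
#' neural gain. Amplitudes are sub-microvolt, as for a normal-hearing adult
#' click ABR.
#'
#' @param profile A [subject_profile].
#' @param fs Sampling rate, Hz.
#' @param duration_ms Epoch length, ms (default the 24.7 ms click epoch).
#' @return A [waveform] in microvolts.
#' @export
abr_template <- function(profile, fs = 20000, duration_ms = 24.7) {
  stopifnot(inherits(profile, "subject_profile"))
  lat <- profile$abr_latencies
  if (any(lat <= 0) || any(lat >= duration_ms)) {
    stop("ABR wave latencies must fall inside the epoch")
  }
  t <- seq(0, by = 1000 / fs, length.out = round(duration_ms * fs / 1000))
  amps <- c(0.12, 0.16, 0.28)          # waves I, III, V (uV at unit gain)
  sds <- c(0.25, 0.32, 0.45)           # Gaussian widths (ms)
  x <- numeric(length(t))
  for (k in 1:3) x <- x + amps[k] * exp(-(t - lat[k])^2 / (2 * sds[k]^2))
  waveform(profile$neural_gain * x, fs = fs, t0_ms = 0)
}

# unit-amplitude biphasic difference-of-Gaussians PAM shape, placed and
# scaled on the recording epoch grid so that the BAND-PASSED epoch (exactly
# what the measurement pipeline sees) peaks at `peak_latency_ms` with a
# peak-to-peak of 1 inside the 8-18 ms artifact search window
pam_shape_unit <- function(peak_latency_ms, fs, duration_ms,
                           sigma_ms = 1.6, sep_ms = 2.5) {
  key <- sprintf("pamshape_%g_%g_%g", peak_latency_ms, fs, duration_ms)
  cached <- template_cache[[key]]
  if (!is.null(cached)) return(cached)
  t <- seq(0, by = 1000 / fs, length.out = round(duration_ms * fs / 1000))
  shape <- function(center) {
    exp(-(t - center)^2 / (2 * sigma_ms^2)) -
      exp(-(t - center - sep_ms)^2 / (2 * sigma_ms^2))
  }
  meas_win <- c(8, 18)
  f0 <- bandpass_notch(waveform(shape(peak_latency_ms), fs = fs, t0_ms = 0))
  idx <- window_indices(f0, meas_win)
  peak_t <- time_axis_ms(f0)[idx[which.max(f0$samples[idx])]]
  # translate so the filtered peak lands on the requested latency
  center <- peak_latency_ms - (peak_t - peak_latency_ms)
  w1 <- waveform(shape(center), fs = fs, t0_ms = 0)
  f1 <- bandpass_notch(w1)
  p2p <- max(f1$samples[idx]) - min(f1$samples[idx])
  out <- waveform(w1$samples / p2p, fs = fs, t0_ms = 0)
  template_cache[[key]] <- out
  out
}

#' PAM artifact wavelet for one subject and gaze condition
#'
#' Biphasic (difference-of-Gaussians) wavelet whose maximal positive
#' deflection sits at the subject's PAM peak latency (12.5-15 ms) and whose
#' band-passed peak-to-peak amplitude equals
#' `pam_base_amp * gaze_gain(theta)`. The wavelet is wide enough that its
#' magnitude spectrum at 200 Hz lies strictly below that at 100 Hz, the
#' mechanism by which PAM contamination of the FFR declines with stimulus
#' frequency.
#'
#' @param profile A [subject_profile].
#' @param gaze_theta Gaze angle in degrees (default +70, maximal
#'   ipsilateral gaze).
#' @param structure An [effect_structure] for the gaze-gain parameters.
#' @param fs Sampling rate, Hz.
#' @param duration_ms Epoch length, ms.
#' @return A [waveform] in microvolts.
#' @export
pam_wavelet <- function(profile, gaze_theta = 70,
                        structure = effect_structure(),
                        fs = 20000, duration_ms = 24.7) {
  stopifnot(inherits(profile, "subject_profile"))
  g <- gaze_gain(gaze_theta, structure, exponent = profile$gaze_exponent)
  base <- pam_shape_unit(profile$pam_peak_latency, fs, duration_ms)
  waveform(profile$pam_base_amp * g * base$samples, fs = fs, t0_ms = 0)
}

# Sustained phase-locked neural FFR template at unit RMS (over the 10-110 ms
# steady-state window): a harmonic stack at the stimulus F0 with fixed
# scattered phases, delayed by the neural transmission lag and gated by
# raised-cosine onset/offset ramps. This is the genuinely neurogenic portion
# of the FFR; it is deliberately NOT an iterated click ABR, because the
# sustained response carries phase-locked structure that a repeated onset
# transient does not predict.
neural_ffr_unit <- function(f0, fs = 20000, duration_ms = 127,
                            delay_ms = 8, stim_dur_ms = 100,
                            ramp_ms = 5, max_harmonic_hz = 850) {
  key <- sprintf("ffrneural_%g_%g_%g", f0, fs, duration_ms)
  cached <- template_cache[[key]]
  if (!is.null(cached)) return(cached)
  t <- seq(0, by = 1000 / fs, length.out = round(duration_ms * fs / 1000))
  n_h <- max(1, floor(max_harmonic_hz / f0))
  x <- numeric(length(t))
  tt <- (t - delay_ms) / 1000
  for (h in seq_len(n_h)) {
    x <- x + h^(-0.8) * sin(2 * pi * h * f0 * tt + NEURAL_PHASES[h])
  }
  # raised-cosine gate over [delay, delay + stimulus duration]
  env <- numeric(length(t))
  rise <- t >= delay_ms & t < delay_ms + ramp_ms
  hold <- t >= delay_ms + ramp_ms & t <= delay_ms + stim_dur_ms
  fall <- t > delay_ms + stim_dur_ms & t <= delay_ms + stim_dur_ms + ramp_ms
  env[rise] <- 0.5 * (1 - cos(pi * (t[rise] - delay_ms) / ramp_ms))
  env[hold] <- 1
  env[fall] <- 0.5 * (1 + cos(pi * (t[fall] - delay_ms - stim_dur_ms) / ramp_ms))
  x <- x * env
  w <- waveform(x, fs = fs, t0_ms = 0)
  w$samples <- w$samples / rms_amplitude(w, c(10, min(110, duration_ms - 1)))
  template_cache[[key]] <- w
  w
}

# exactly band-limited Gaussian noise, synthesized in the frequency domain so
# that its spectrum is confined to `band` and its marginal sd is `sd` exactly
band_limited_noise <- function(n, fs, sd, band = c(50, 3000)) {
  if (sd == 0) return(numeric(n))
  freqs <- (seq_len(n) - 1) * fs / n
  half <- 2:(floor(n / 2))                       # exclude DC and Nyquist
  in_band <- half[freqs[half] >= band[1] & freqs[half] <= band[2]]
  k <- length(in_band)
  if (k == 0L) stop("noise band contains no FFT bins at this length")
  sigma_s <- sd * n / (2 * sqrt(k))
  S <- complex(real = numeric(n), imaginary = numeric(n))
  S[in_band] <- complex(real = stats::rnorm(k, 0, sigma_s),
                        imaginary = stats::rnorm(k, 0, sigma_s))
  S[n - in_band + 2] <- Conj(S[in_band])
  Re(stats::fft(S, inverse = TRUE)) / n
}

# per-package template cache (templates are deterministic; caching keeps the
# averaged-mode simulator fast)
template_cache <- new.env(parent = emptyenv())
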