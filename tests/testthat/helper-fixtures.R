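# shared fixtures: noise-free and deterministic variants of the generator

quiet_structure <- function(...) {
  effect_structure(noise_sd = 0, pam_state_sd = 0, pam_pulse_jitter_sd = 0,
                   ...)
}

# a deterministic mid-range listener
fixed_profile <- function(pam = 2.38, gain = 1, noise_sd = 0,
                          pam_lat = 13.75) {
  subject_profile(subject_id = "sX", music_years = 6.5, pam_base_amp = pam,
                  neural_gain = gain, pam_peak_latency = pam_lat,
                  noise_sd = noise_sd)
}

# brute-force linear convolution oracle (O(n*m) superposition sum)
conv_oracle <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] != 0) {
      out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
    }
  }
  out
}

# brute-force Pearson-at-every-lag cross-correlation oracle
xcorr_oracle <- function(xa, xb, max_lag) {
  best <- -Inf; best_lag <- NA_integer_
  for (k in -max_lag:max_lag) {
    if (k >= 0) {
      sb <- xb[(1 + k):length(xb)]; sa <- xa[seq_along(sb)]
    } else {
      sa <- xa[(1 - k):length(xa)]; sb <- xb[seq_along(sa)]
    }
    n <- min(length(sa), length(sb))
    r <- suppressWarnings(stats::cor(sa[1:n], sb[1:n]))
    if (!is.na(r) && r > best) { best <- r; best_lag <- k }
  }
  list(r = best, lag = best_lag)
}

# access to the internal deterministic signal constructor (click condition)
condition_signal_for_test <- function(profile, struct, channel) {
  pamffr:::condition_signal(profile, "click", stim_spec(), 70, struct, channel)
}
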