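test_that("deriving from a unit impulse returns the pulse train", {
  fs <- 20000
  imp <- waveform(c(1, numeric(199)), fs = fs)
  spec <- stim_spec(f0 = 100)
  drv <- derive_ffr(imp, spec)
  train <- make_pulse_train(spec)
  n <- length(train$samples)
  expect_equal(drv$samples[1:n], train$samples)
  expect_true(all(drv$samples[(n + 1):length(drv$samples)] %in% c(0, 1)))
  expect_equal(length(drv$samples), round(0.127 * fs))
})

test_that("derive_ffr equals the brute-force superposition oracle", {
  fs <- 20000
  set.seed(12)
  for (f0 in c(100, 200, 400)) {
    src <- rnorm(30)
    spec <- stim_spec(f0 = f0, duration_ms = 20)
    got <- derive_ffr(waveform(src, fs), spec, epoch_ms = 30)
    # oracle: place one copy of the source at each pulse time and sum
    n_out <- round(0.030 * fs)
    want <- numeric(n_out)
    pulses <- which(make_pulse_train(spec)$samples != 0)
    for (p in pulses) {
      span <- p:min(n_out, p + length(src) - 1L)
      want[span] <- want[span] + src[seq_along(span)]
    }
    expect_equal(got$samples, want, tolerance = 1e-10)
  }
})

test_that("derive_ffr is linear and onset-locked (no circular wrap)", {
  src <- pam_wavelet(fixed_profile(), 70, quiet_structure())
  spec <- stim_spec(f0 = 100)
  d1 <- derive_ffr(src, spec)
  src3 <- waveform(3 * src$samples, src$fs)
  expect_equal(derive_ffr(src3, spec)$samples, 3 * d1$samples,
               tolerance = 1e-12)
  # nothing before the first pulse convolved with the source's leading zeros
  lead <- sum(cumsum(abs(src$samples)) == 0)
  expect_equal(d1$samples[seq_len(lead)], numeric(lead))
  expect_error(derive_ffr(waveform(rnorm(10), 10000), spec), "sampling rates")
})

test_that("the derived FFR is T-periodic in steady state", {
  src <- pam_wavelet(fixed_profile(), 70, quiet_structure())
  drv <- derive_ffr(src, stim_spec(f0 = 100))
  fs <- drv$fs
  Tn <- fs / 100                                 # one period in samples
  i <- pamffr:::window_indices(drv, c(30, 80))
  expect_equal(drv$samples[i + Tn], drv$samples[i], tolerance = 1e-9)
})

test_that("score_model reports r, lag and r^2 consistently", {
  src <- pam_wavelet(fixed_profile(), 70, quiet_structure())
  drv <- derive_ffr(src, stim_spec(f0 = 100))
  self <- score_model(drv, drv)
  expect_equal(self$r_max, 1, tolerance = 1e-12)
  expect_equal(self$r_squared, 1, tolerance = 1e-12)
  set.seed(4)
  noise <- waveform(rnorm(length(drv$samples)), drv$fs)
  null <- score_model(drv, noise)
  expect_lt(null$r_squared, 0.2)
  expect_equal(null$r_squared, null$r_max^2)
})

test_that("cohort model fit is internally consistent and flags missing data", {
  co <- sample_cohort(4, seed = 21)
  rec <- simulate_recordings(co, gaze_positions = 5, seed = 22)
  fit <- cohort_model_fit(rec)
  expect_equal(fit$per_subject$r_squared, fit$per_subject$r^2)
  expect_equal(fit$mean_r, mean(fit$per_subject$r))
  expect_equal(fit$mean_r_squared, mean(fit$per_subject$r^2))
  expect_true(all(abs(fit$per_subject$r) <= 1))
  expect_true(all(abs(fit$per_subject$lag_ms) <= 20))

  # a subject with a missing FFR channel is dropped with a warning
  rec$waves[["s02|f0_100|g5|mastoid"]] <- NULL
  expect_warning(fit2 <- cohort_model_fit(rec), "missing")
  expect_equal(nrow(fit2$per_subject), 3L)

  # isolated-PAM source mode runs and stays within bounds
  fit3 <- cohort_model_fit(simulate_recordings(co, gaze_positions = 5,
                                               seed = 22),
                           source = "isolated_pam")
  expect_true(all(abs(fit3$per_subject$r) <= 1))
})

test_that("a noise-free pure-PAM cohort is perfectly explained by the model", {
  struct <- quiet_structure(snr_neural_pam = 0)
  co <- sample_cohort(3, struct, seed = 31)
  for (i in seq_along(co$subjects)) co$subjects[[i]]$neural_gain <- 0
  rec <- simulate_recordings(co, gaze_positions = 5, seed = 32)
  fit <- cohort_model_fit(rec)
  # not exactly 1: band-pass edge handling differs slightly between
  # filtering-then-convolving and convolving-then-filtering
  expect_gt(fit$mean_r, 0.995)
})
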