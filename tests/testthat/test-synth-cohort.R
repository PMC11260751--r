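test_that("cohorts and recordings are bit-identical under a fixed seed", {
  c1 <- sample_cohort(5, seed = 123)
  c2 <- sample_cohort(5, seed = 123)
  expect_identical(c1, c2)
  c3 <- sample_cohort(5, seed = 124)
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))

  small <- sample_cohort(3, seed = 9)
  r1 <- simulate_recordings(small, gaze_positions = 5, seed = 17)
  r2 <- simulate_recordings(small, gaze_positions = 5, seed = 17)
  expect_identical(lapply(r1$waves, `[[`, "samples"),
                   lapply(r2$waves, `[[`, "samples"))
})

test_that("sampled profiles respect the planted population structure", {
  big <- sample_cohort(400, seed = 31)
  df <- as.data.frame(big)
  expect_true(all(df$pam_base_amp >= 0.18 & df$pam_base_amp <= 9.7))
  expect_true(all(df$music_years >= 0 & df$music_years <= 23))
  expect_true(all(df$pam_peak_latency >= 12.5 & df$pam_peak_latency <= 15))
  # population music-training distribution: mean 6.5 y, sd 7.3 y, mass at 0
  expect_equal(mean(df$music_years), 6.5, tolerance = 0.15)
  expect_equal(sd(df$music_years), 7.3, tolerance = 0.1)
  expect_gt(mean(df$music_years == 0), 0.2)
  for (s in big$subjects) expect_true(all(diff(s$abr_latencies) > 0))
})

test_that("infeasible path coefficients are refused", {
  expect_error(effect_structure(a_music_pam = 1.2), "path coefficients")
  expect_error(sample_cohort(2), "at least 3")
})

test_that("gaze gain is normalized, symmetric and floor-limited", {
  s <- effect_structure(gaze_floor = 0.25, gaze_exponent = 1.3)
  expect_equal(gaze_gain(70, s), 1)
  expect_equal(gaze_gain(-70, s), 1)
  expect_equal(gaze_gain(0, s), 0.25)
  th <- seq(0, 70, by = 5)
  expect_equal(gaze_gain(th, s), gaze_gain(-th, s))
  expect_true(all(diff(gaze_gain(th, s)) >= 0))
  expect_error(gaze_gain(80, s), "within")
})

test_that("PAM wavelet scales with gaze gain and subject amplitude", {
  s <- effect_structure(gaze_floor = 0.25, gaze_exponent = 1)
  prof <- fixed_profile(pam = 2.38)
  prof$gaze_exponent <- 1
  w70 <- bandpass_notch(pam_wavelet(prof, 70, s))
  w0 <- bandpass_notch(pam_wavelet(prof, 0, s))
  expect_equal(peak_to_peak(w70, c(8, 18)), 2.38, tolerance = 1e-6)
  expect_equal(peak_to_peak(w0, c(8, 18)), 0.25 * 2.38, tolerance = 1e-6)
})

test_that("generator output is linear in pam_base_amp and neural_gain", {
  s <- quiet_structure()
  base <- fixed_profile(pam = 1.5, gain = 0.8)
  dbl_pam <- fixed_profile(pam = 3.0, gain = 0.8)
  dbl_gain <- fixed_profile(pam = 1.5, gain = 1.6)
  sig <- function(p, ch) condition_signal_for_test(p, s, ch)
  # mastoid click = ABR + PAM; doubling PAM doubles only the difference
  m1 <- sig(base, "mastoid"); n1 <- sig(base, "neck")
  m2 <- sig(dbl_pam, "mastoid"); n2 <- sig(dbl_pam, "neck")
  expect_lt(max(abs((m2$samples - n2$samples) -
                      2 * (m1$samples - n1$samples))), 1e-12)
  # doubling neural gain doubles the neck (neural-only) channel
  n3 <- sig(dbl_gain, "neck")
  expect_lt(max(abs(n3$samples - 2 * n1$samples)), 1e-12)
  # zero neural gain gives an all-zero ABR template
  expect_equal(abr_template(fixed_profile(gain = 0))$samples,
               numeric(length(abr_template(base)$samples)))
})

test_that("neck-channel FFRs are invariant to gaze; mastoid FFRs are not", {
  co <- sample_cohort(3, quiet_structure(), seed = 5)
  rec <- simulate_recordings(co, seed = 5)
  for (sid in c("s01", "s02", "s03")) {
    n1 <- get_response(rec, sid, "f0_100", 1, "neck")
    n3 <- get_response(rec, sid, "f0_100", 3, "neck")
    n5 <- get_response(rec, sid, "f0_100", 5, "neck")
    expect_equal(n1$samples, n3$samples)
    expect_equal(n1$samples, n5$samples)
    m3 <- get_response(rec, sid, "f0_100", 3, "mastoid")
    m5 <- get_response(rec, sid, "f0_100", 5, "mastoid")
    expect_gt(rms_amplitude(m5, c(10, 110)), rms_amplitude(m3, c(10, 110)))
  }
})

test_that("the PAM wavelet spectrum declines from 100 to 200 Hz", {
  w <- pam_wavelet(fixed_profile(), 70, quiet_structure())
  s100 <- spectrum_amplitude(w, 100, c(0, 24.65))
  s200 <- spectrum_amplitude(w, 200, c(0, 24.65))
  expect_lt(s200, s100)
  # consequence: the PAM-derived component is weaker at the 200 Hz F0 bin
  d100 <- derive_ffr(w, stim_spec(f0 = 100))
  d200 <- derive_ffr(w, stim_spec(f0 = 200))
  expect_lt(spectrum_amplitude(d200, 200), spectrum_amplitude(d100, 100))
})

test_that("a null effect structure yields null cohort correlations", {
  rs <- sapply(1:16, function(s) {
    df <- as.data.frame(sample_cohort(
      60, effect_structure(a_music_pam = 0, b_music_neural = 0), seed = s))
    c(cor(df$music_years, log(df$pam_base_amp)),
      cor(df$music_years, log(df$neural_gain)))
  })
  expect_lt(abs(mean(rs[1, ])), 0.08)
  expect_lt(abs(mean(rs[2, ])), 0.08)
})

test_that("the pipeline recovers planted PAM amplitudes on a noise-free cohort", {
  struct <- quiet_structure()
  co <- sample_cohort(5, struct, seed = 77)
  rec <- simulate_recordings(co, gaze_positions = 5, seed = 78)
  mt <- metrics_table(rec)
  g5 <- mt[mt$channel == "mastoid" & mt$gaze_position == 5, ]
  ids <- sapply(co$subjects, `[[`, "subject_id")
  planted <- sapply(co$subjects, `[[`, "pam_base_amp")
  expect_equal(g5$pam_p2p[match(ids, g5$subject_id)], planted,
               tolerance = 1e-6)
  planted_lat <- sapply(co$subjects, `[[`, "pam_peak_latency")
  expect_equal(g5$pam_latency[match(ids, g5$subject_id)], planted_lat,
               tolerance = 0.051)
})
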