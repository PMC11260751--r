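test_that("the notch removes line noise and the passband is transparent", {
  fs <- 20000
  t <- seq(0, 2, by = 1 / fs)
  hum <- waveform(sin(2 * pi * 60 * t), fs = fs)
  out <- bandpass_notch(hum)
  mid <- c(500, 1500)                    # central 1 s, away from edges
  expect_lt(rms_amplitude(out, mid) / rms_amplitude(hum, mid), 0.05)

  tone <- waveform(sin(2 * pi * 100 * t), fs = fs)
  out100 <- bandpass_notch(tone)
  ratio <- rms_amplitude(out100, mid) / rms_amplitude(tone, mid)
  expect_gt(ratio, 0.90)
  expect_lt(ratio, 1.10)

  zero <- bandpass_notch(waveform(numeric(1000), fs = fs))
  expect_equal(zero$samples, numeric(1000))

  expect_error(bandpass_notch(waveform(rnorm(100), fs = 4000)), "too low")
})

test_that("amplitude rejection keeps exactly the clean sweeps", {
  prof <- fixed_profile(noise_sd = 1)
  sw <- synth_sweeps(prof, stim_spec(), gaze_theta = 70, channel = "mastoid",
                     n_sweeps = 2200, seed = 11, structure = quiet_structure(),
                     stim_type = "click", contaminate_n = 200)
  avg <- reject_and_average(sw, epoch_spec("ABR"))
  expect_equal(avg$n_sweeps_used, 2000L)
  expect_equal(avg$n_sweeps_input, 2200L)
})

test_that("averaging equals the brute-force mean and is permutation invariant", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rnorm(30 * 50, sd = 25), nrow = 30)
    ss <- sweep_set(m, fs = 20000, channel = "neck")
    spec <- epoch_spec("ABR", reject_threshold_uv = 50)
    keep <- apply(abs(m), 1, max) <= 50
    if (!any(keep)) next
    avg <- reject_and_average(ss, spec)
    expect_equal(avg$samples, colMeans(m[keep, , drop = FALSE]))
    expect_equal(avg$n_sweeps_used, sum(keep))
    # permutation of sweeps leaves the average unchanged
    perm <- sample(nrow(m))
    avg2 <- reject_and_average(sweep_set(m[perm, ], fs = 20000,
                                         channel = "neck"), spec)
    expect_equal(avg2$samples, avg$samples)
  }
  # threshold = Inf keeps everything: plain mean
  m <- matrix(rnorm(10 * 20, sd = 100), nrow = 10)
  avg <- reject_and_average(sweep_set(m, fs = 20000, channel = "neck"),
                            epoch_spec("ABR", reject_threshold_uv = Inf))
  expect_equal(avg$samples, colMeans(m))
})

test_that("identical noise-free sweeps average to a single sweep", {
  prof <- fixed_profile()
  sw <- synth_sweeps(prof, stim_spec(), 70, "mastoid", n_sweeps = 8,
                     seed = 3, structure = quiet_structure(),
                     stim_type = "click")
  avg <- reject_and_average(sw, epoch_spec("ABR"))
  expect_equal(avg$samples, sw$epochs[1, ])
})

test_that("rejection of every sweep raises an error naming the threshold", {
  m <- matrix(100, nrow = 4, ncol = 10)
  expect_error(reject_and_average(sweep_set(m, fs = 20000, channel = "neck"),
                                  epoch_spec("ABR")),
               "50")
})

test_that("channel subtraction isolates the planted PAM wavelet", {
  struct <- quiet_structure()
  prof <- fixed_profile(pam = 3.1)
  mast <- synth_sweeps(prof, stim_spec(), 70, "mastoid", 1, seed = 1,
                       structure = struct, stim_type = "click")
  neck <- synth_sweeps(prof, stim_spec(), 70, "neck", 1, seed = 1,
                       structure = struct, stim_type = "click")
  am <- reject_and_average(mast, epoch_spec("ABR"))
  an <- reject_and_average(neck, epoch_spec("ABR"))
  diffw <- isolate_pam(am, an)
  planted <- pam_wavelet(prof, 70, struct)
  expect_equal(diffw$samples, planted$samples, tolerance = 1e-10)

  # identical inputs give a zero trace
  wm <- waveform(am$samples, am$fs)
  expect_equal(isolate_pam(wm, wm)$samples, numeric(length(am$samples)))

  # linearity: scaling both inputs scales the difference
  am3 <- am; am3$samples <- 3 * am$samples
  an3 <- an; an3$samples <- 3 * an$samples
  expect_equal(isolate_pam(am3, an3)$samples, 3 * diffw$samples)

  # mismatched grids are refused
  short <- waveform(am$samples[1:100], fs = am$fs)
  expect_error(isolate_pam(am, short), "mismatched")
})
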