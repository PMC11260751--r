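# Waveform-level synthesis of two-channel evoked recordings.
#
# Channel model (microvolts):
#   click runs : mastoid = gain*ABR + PAM(theta),     neck = gain*ABR
#   FFR runs   : mastoid = -gain*FFRn + conv(PAM(theta), pulse train)
#                neck    = +gain*FFRn
# where FFRn is the sustained phase-locked neural template and the mastoid /
# neck sign flip reproduces the ~180 degree phase shift seen between the two
# montages for sustained responses. The transient click ABR appears with the
# same sign in both channels, so channel subtraction cancels it and isolates
# the PAM artifact.

FFR_EPOCH_MS <- 127
ABR_EPOCH_MS <- 24.7

# steady-state RMS of the convolved PAM component for a cohort-mean-sized
# (2.38 uV) artifact at maximal gaze; reference scale for snr_neural_pam
ref_pam_conv_rms <- function(stim) {
  key <- sprintf("refconv_%g_%g", stim$f0, stim$fs)
  cached <- template_cache[[key]]
  if (!is.null(cached)) return(cached)
  shape <- pam_shape_unit(13.75, stim$fs, ABR_EPOCH_MS)
  train <- make_pulse_train(stim)
  n_out <- round(FFR_EPOCH_MS * stim$fs / 1000)
  conv <- lin_conv(shape$samples * 2.38, train$samples)
  conv <- c(conv, numeric(max(0, n_out - length(conv))))[seq_len(n_out)]
  val <- rms_amplitude(waveform(conv, stim$fs), c(10, 110))
  template_cache[[key]] <- val
  val
}

# deterministic (noise-free) signal for one subject / condition / channel
condition_signal <- function(profile, stim_type = c("click", "train"),
                             stimulus = stim_spec(), gaze_theta = 70,
                             structure = effect_structure(),
                             channel = c("mastoid", "neck"),
                             pam_scale = 1, pulse_mod = NULL) {
  stim_type <- match.arg(stim_type)
  channel <- match.arg(channel)
  fs <- stimulus$fs
  if (stim_type == "click") {
    neural <- abr_template(profile, fs = fs, duration_ms = ABR_EPOCH_MS)
    if (channel == "neck") return(neural)
    pam <- pam_wavelet(profile, gaze_theta, structure, fs = fs,
                       duration_ms = ABR_EPOCH_MS)
    return(waveform(neural$samples + pam_scale * pam$samples, fs, 0))
  }
  n_out <- round(FFR_EPOCH_MS * fs / 1000)
  unit <- neural_ffr_unit(stimulus$f0, fs = fs, duration_ms = FFR_EPOCH_MS)
  neural_amp <- profile$neural_gain * structure$snr_neural_pam *
    ref_pam_conv_rms(stimulus)
  neural <- neural_amp * unit$samples
  if (channel == "neck") return(waveform(neural, fs, 0))
  pam <- pam_wavelet(profile, gaze_theta, structure, fs = fs,
                     duration_ms = ABR_EPOCH_MS)
  train <- make_pulse_train(stimulus)
  conv <- lin_conv(pam_scale * pam$samples, train$samples)
  conv <- c(conv, numeric(max(0, n_out - length(conv))))[seq_len(n_out)]
  if (!is.null(pulse_mod)) {
    nz <- which(train$samples != 0)
    if (length(pulse_mod) != length(nz)) {
      stop("pulse_mod must have one factor per stimulus pulse")
    }
    mtrain <- train
    mtrain$samples[nz] <- mtrain$samples[nz] * pulse_mod
    mconv <- lin_conv(pam_scale * pam$samples, mtrain$samples)
    mconv <- c(mconv, numeric(max(0, n_out - length(mconv))))[seq_len(n_out)]
    # per-pulse motor-unit variability redistributes energy across periods;
    # run-level amplitude is governed by the muscle-state factor alone, so
    # rescale the modulated train to the steady-state RMS of the plain one
    wseg <- function(x) {
      i0 <- round(10 * fs / 1000) + 1L; i1 <- round(110 * fs / 1000) + 1L
      sqrt(mean(x[i0:i1]^2))
    }
    r_plain <- wseg(conv); r_mod <- wseg(mconv)
    conv <- if (r_mod > 0) mconv * (r_plain / r_mod) else mconv
  }
  waveform(conv - neural, fs, 0)
}

# mean-one log-normal draw(s)
rlnorm1 <- function(n, sdlog) exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))

#' Simulate raw sweeps for one subject and condition
#'
#' Each sweep is the deterministic condition signal plus fresh band-limited
#' (50-3,000 Hz) Gaussian noise with the subject's per-sweep noise sd.
#' Optionally a subset of sweeps receives a planted +/-60 uV excursion so
#' that amplitude rejection can be exercised.
#'
#' @param profile A [subject_profile].
#' @param stimulus A [stim_spec] (for `stim_type = "train"`) or the click
#'   spec (its `f0` is ignored for clicks).
#' @param gaze_theta Gaze angle in degrees.
#' @param channel `"mastoid"` or `"neck"`.
#' @param n_sweeps Number of sweeps to generate.
#' @param seed Integer seed; the same seed reproduces the sweeps
#'   bit-identically.
#' @param structure An [effect_structure].
#' @param stim_type `"click"` (0-24.7 ms epoch) or `"train"` (0-127 ms
#'   epoch).
#' @param contaminate_n Number of sweeps to contaminate with a +/-60 uV
#'   excursion (default 0).
#' @param pam_scale Multiplicative run-level muscle-state factor (default 1).
#' @param pulse_mod Optional per-pulse PAM amplitude factors for train runs
#'   (fixed across sweeps within the run; default none).
#' @return A [sweep_set].
#' @export
synth_sweeps <- function(profile, stimulus = stim_spec(), gaze_theta = 70,
                         channel = c("mastoid", "neck"), n_sweeps = 100,
                         seed = 1L, structure = effect_structure(),
                         stim_type = c("train", "click"),
                         contaminate_n = 0, pam_scale = 1, pulse_mod = NULL) {
  channel <- match.arg(channel)
  stim_type <- match.arg(stim_type)
  if (n_sweeps < 1) stop("n_sweeps must be at least 1")
  sig <- condition_signal(profile, stim_type, stimulus, gaze_theta,
                          structure, channel, pam_scale, pulse_mod)
  n <- length(sig$samples)
  epochs <- withr::with_seed(as.integer(seed), {
    m <- matrix(sig$samples, nrow = n_sweeps, ncol = n, byrow = TRUE)
    if (profile$noise_sd > 0) {
      noise <- matrix(0, n_sweeps, n)
      for (i in seq_len(n_sweeps)) {
        noise[i, ] <- band_limited_noise(n, sig$fs, profile$noise_sd)
      }
      m <- m + noise
    }
    if (contaminate_n > 0) {
      bad <- sample.int(n_sweeps, contaminate_n)
      at <- max(1L, round(n / 2))
      span <- at:min(n, at + 4L)
      for (i in bad) m[i, span] <- m[i, span] + 60 * sample(c(-1, 1), 1)
    }
    m
  })
  sweep_set(epochs, fs = sig$fs, t0_ms = 0, channel = channel,
            subject_id = profile$subject_id,
            condition = list(stim_type = stim_type, f0 = stimulus$f0,
                             gaze_theta = gaze_theta))
}

#' Simulate a full cohort of averaged evoked recordings
#'
#' Generates, for every subject x stimulus x gaze position x channel, the
#' ensemble average of `n_sweeps` sweeps. In `"average"` mode (the default)
#' the average is synthesized directly as signal plus band-limited noise with
#' sd `noise_sd / sqrt(n_sweeps)`, which is distributionally identical to
#' averaging `n_sweeps` individually simulated clean sweeps while being fast
#' enough for seed-replicated experiments. `"sweeps"` mode generates and
#' averages raw sweeps through [reject_and_average()] (slow; intended for
#' small validation runs).
#'
#' Each subject x gaze x stimulus run receives a multiplicative log-normal
#' muscle-state factor (sd `structure$pam_state_sd`) on its PAM amplitude,
#' reflecting run-to-run variation in tonic muscle tension.
#'
#' @param cohort A [pam_cohort].
#' @param f0s Fundamental frequencies of the FFR stimuli to run (default
#'   100 Hz; the reference study also used 200 Hz).
#' @param gaze_positions Integer gaze positions 1-5 (angles -70, -35, 0,
#'   +35, +70 degrees).
#' @param channels Channels to record.
#' @param n_sweeps Sweeps per condition (default 2000).
#' @param mode `"average"` or `"sweeps"` (see above).
#' @param seed Integer seed for all noise and muscle-state draws (defaults
#'   to the cohort seed).
#' @param include_click Include the click (ABR) runs needed for PAM
#'   isolation (default TRUE).
#' @param click_gaze_positions Gaze positions for the click runs (defaults
#'   to `gaze_positions`; restrict to `5` when only the maximal-gaze PAM
#'   trait measurement is needed).
#' @param ffr_channels Channels for the FFR (train) runs (defaults to
#'   `channels`; the click runs always use `channels` since PAM isolation
#'   needs the mastoid/neck pair).
#' @return An object of class `ffr_recordings`: `index` (data frame), named
#'   list `waves` of `averaged_response` objects, plus the cohort and run
#'   metadata.
#' @examples
#' \donttest{
#' rec <- simulate_recordings(sample_cohort(3, seed = 1), seed = 1)
#' }
#' @export
simulate_recordings <- function(cohort, f0s = 100, gaze_positions = 1:5,
                                channels = c("mastoid", "neck"),
                                n_sweeps = 2000,
                                mode = c("average", "sweeps"),
                                seed = cohort$seed, include_click = TRUE,
                                click_gaze_positions = gaze_positions,
                                ffr_channels = channels) {
  stopifnot(inherits(cohort, "pam_cohort"))
  mode <- match.arg(mode)
  struct <- cohort$structure
  stims <- list()
  if (include_click) stims[["click"]] <- stim_spec(f0 = 100)
  for (f0 in f0s) stims[[sprintf("f0_%g", f0)]] <- stim_spec(f0 = f0)
  waves <- list()
  rows <- list()
  withr::with_seed(as.integer(seed), {
    for (prof in cohort$subjects) {
      for (stim_name in names(stims)) {
        stim <- stims[[stim_name]]
        stim_type <- if (stim_name == "click") "click" else "train"
        gps <- if (stim_type == "click") click_gaze_positions else gaze_positions
        chans <- if (stim_type == "click") channels else ffr_channels
        for (gp in gps) {
          theta <- GAZE_ANGLES[gp]
          pam_scale <- rlnorm1(1, struct$pam_state_sd)
          pulse_mod <- NULL
          if (stim_type == "train") {
            n_pulses <- ceiling(stim$duration_ms * stim$f0 / 1000)
            pulse_mod <- rlnorm1(n_pulses, struct$pam_pulse_jitter_sd)
          }
          for (ch in chans) {
            sig <- condition_signal(prof, stim_type, stim, theta, struct,
                                    ch, pam_scale, pulse_mod)
            if (mode == "average") {
              avg <- sig
              if (prof$noise_sd > 0) {
                avg$samples <- avg$samples +
                  band_limited_noise(length(sig$samples), sig$fs,
                                     prof$noise_sd / sqrt(n_sweeps))
              }
              avg$n_sweeps_used <- n_sweeps
              avg$n_sweeps_input <- n_sweeps
              avg$channel <- ch
              avg$subject_id <- prof$subject_id
              avg$condition <- list(stim_type = stim_type, f0 = stim$f0,
                                    gaze_position = gp, gaze_theta = theta)
              class(avg) <- c("averaged_response", class(avg))
            } else {
              sw <- synth_sweeps(prof, stim, theta, ch, n_sweeps,
                                 seed = stats::runif(1, 1, 2^30),
                                 structure = struct, stim_type = stim_type,
                                 pam_scale = pam_scale, pulse_mod = pulse_mod)
              spec <- epoch_spec(if (stim_type == "click") "ABR" else "FFR",
                                 fs = stim$fs)
              avg <- reject_and_average(sw, spec)
              avg$condition <- c(avg$condition, list(gaze_position = gp))
            }
            key <- sprintf("%s|%s|g%d|%s", prof$subject_id, stim_name, gp, ch)
            waves[[key]] <- avg
            rows[[key]] <- data.frame(
              subject_id = prof$subject_id, stim = stim_name,
              f0 = if (stim_type == "click") NA_real_ else stim$f0,
              gaze_position = gp, angle = theta, channel = ch, key = key,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  })
  out <- list(index = do.call(rbind, rows), waves = waves, cohort = cohort,
              n_sweeps = n_sweeps, mode = mode, seed = as.integer(seed),
              f0s = f0s)
  class(out) <- "ffr_recordings"
  out
}

#' @export
print.ffr_recordings <- function(x, ...) {
  cat(sprintf("<ffr_recordings> %d averaged responses, %d subjects, mode %s (seed %d)\n",
              length(x$waves), length(x$cohort$subjects), x$mode, x$seed))
  invisible(x)
}

#' Fetch one averaged response from a recordings object
#'
#' @param rec An `ffr_recordings` object.
#' @param subject_id Subject label (e.g. `"s01"`).
#' @param stim Stimulus label: `"click"` or `"f0_100"` / `"f0_200"`.
#' @param gaze_position Gaze position 1-5.
#' @param channel `"mastoid"` or `"neck"`.
#' @return An `averaged_response`.
#' @export
get_response <- function(rec, subject_id, stim, gaze_position, channel) {
  key <- sprintf("%s|%s|g%d|%s", subject_id, stim, gaze_position, channel)
  w <- rec$waves[[key]]
  if (is.null(w)) stop(sprintf("no recording for %s", key))
  w
}

#' Build the per-subject metrics table
#'
#' Runs the measurement stage over a recordings object: band-pass + notch
#' filtering of every average, PAM isolation by channel subtraction of the
#' click runs, then peak-to-peak, RMS, latency and spectral metrics. Rows are
#' subject x gaze x channel x F0.
#'
#' @param rec An `ffr_recordings` object (must include click runs for the
#'   PAM columns).
#' @param pam_window,ffr_window,onset_window Measurement windows in ms.
#' @param measures `"full"` (default) or `"amplitude"`: the latter computes
#'   only the amplitude columns (PAM p2p, FFR rms), skipping latencies and
#'   spectra -- useful for large replication studies.
#' @return A data frame (class `metrics_table`) with columns `subject_id`,
#'   `music_years`, `gaze_position`, `angle`, `channel`, `f0`, `pam_p2p`,
#'   `pam_latency`, `ffr_rms`, `ffr_onset_latency`, `f0_amp`, `h2_amp`,
#'   `h3_amp` (latency/spectral columns are `NA` under
#'   `measures = "amplitude"`).
#' @export
metrics_table <- function(rec, pam_window = c(8, 18),
                          ffr_window = c(10, 110), onset_window = c(6, 12),
                          measures = c("full", "amplitude")) {
  measures <- match.arg(measures)
  stopifnot(inherits(rec, "ffr_recordings"))
  idx <- rec$index
  profiles <- rec$cohort$subjects
  names(profiles) <- vapply(profiles, `[[`, "", "subject_id")
  filt_cache <- new.env(parent = emptyenv())
  filtered <- function(key) {
    f <- filt_cache[[key]]
    if (is.null(f)) {
      f <- bandpass_notch(rec$waves[[key]])
      filt_cache[[key]] <- f
    }
    f
  }
  rows <- list()
  subjects <- unique(idx$subject_id)
  gazes <- sort(unique(idx$gaze_position))
  stim_names <- setdiff(unique(idx$stim), "click")
  has_click <- "click" %in% idx$stim
  for (sid in subjects) {
    music <- profiles[[sid]]$music_years
    for (gp in gazes) {
      pam_p2p <- NA_real_; pam_lat <- NA_real_
      if (has_click) {
        mk <- sprintf("%s|click|g%d|mastoid", sid, gp)
        nk <- sprintf("%s|click|g%d|neck", sid, gp)
        if (!is.null(rec$waves[[mk]]) && !is.null(rec$waves[[nk]])) {
          pam <- isolate_pam(filtered(mk), filtered(nk))
          pam_p2p <- peak_to_peak(pam, pam_window)
          if (measures == "full") pam_lat <- onset_latency(pam, pam_window)
        }
      }
      for (stim_name in stim_names) {
        f0 <- as.numeric(sub("f0_", "", stim_name))
        for (ch in unique(idx$channel)) {
          key <- sprintf("%s|%s|g%d|%s", sid, stim_name, gp, ch)
          if (is.null(rec$waves[[key]])) next
          w <- filtered(key)
          if (measures == "full") {
            sp <- harmonic_amplitudes(w, f0, c(1, 2, 3), ffr_window)
            lat <- onset_latency(w, onset_window)
          } else {
            sp <- rep(NA_real_, 3)
            lat <- NA_real_
          }
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sid, music_years = music, gaze_position = gp,
            angle = GAZE_ANGLES[gp], channel = ch, f0 = f0,
            pam_p2p = pam_p2p, pam_latency = pam_lat,
            ffr_rms = rms_amplitude(w, ffr_window),
            ffr_onset_latency = lat,
            f0_amp = sp[1], h2_amp = sp[2], h3_amp = sp[3],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_table", class(out))
  out
}

#' Aggregated table for the individual-differences analyses
#'
#' Builds the subject x gaze table used by the correlation, regression and
#' mediation analyses: one row per subject and gaze position with the FFR
#' measures of the chosen channel/F0, where the `pam_p2p` column holds each
#' subject's artifact strength -- the isolated-PAM peak-to-peak measured at
#' maximal ipsilateral gaze (position 5) -- replicated across that subject's
#' gaze rows. The isolated PAM at maximal gaze is the per-listener trait
#' measure of reflex size; the FFR rows retain their gaze dependence.
#'
#' @param table A [metrics_table()] data frame.
#' @param channel Channel rows to keep (default `"mastoid"`).
#' @param f0 Stimulus F0 rows to keep (default 100).
#' @param pam_gaze_position Gaze position of the PAM trait measurement
#'   (default 5).
#' @return A data frame with the same columns as the input, `pam_p2p`
#'   replaced by the subject-level measure.
#' @export
aggregated_table <- function(table, channel = "mastoid", f0 = 100,
                             pam_gaze_position = 5) {
  out <- table[table$channel == channel & table$f0 == f0, ]
  ref <- table[table$gaze_position == pam_gaze_position &
                 table$channel == channel & table$f0 == f0, ]
  pam <- ref$pam_p2p
  names(pam) <- ref$subject_id
  out$pam_p2p <- unname(pam[out$subject_id])
  out
}
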