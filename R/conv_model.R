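#' Derive an FFR by convolving a transient response with the pulse train
#'
#' The core of the superposition model: the sustained following response to a
#' periodic click train is modeled as an iterated transient response, i.e.
#' the linear convolution of a single-onset waveform (the subject's
#' PAM-contaminated ABR, or their isolated PAM artifact) with the stimulus
#' impulse train. Overlapping copies superpose additively; the result is
#' truncated to the FFR recording epoch (0-127 ms), with no circular wrap
#' (the physical process is onset-locked).
#'
#' @param source A [waveform] holding the transient response (its epoch must
#'   be shorter than the FFR epoch).
#' @param stimulus A [stim_spec]; its pulse train supplies the periodicity.
#' @param epoch_ms Output epoch length in ms (default 127).
#' @return A [waveform]: the derived FFR.
#' @examples
#' imp <- waveform(c(1, numeric(99)), fs = 20000)
#' d <- derive_ffr(imp, stim_spec(f0 = 100))  # equals the pulse train
#' @export
derive_ffr <- function(source, stimulus = stim_spec(f0 = 100),
                       epoch_ms = FFR_EPOCH_MS) {
  stopifnot(inherits(source, "waveform"), inherits(stimulus, "stim_spec"))
  if (abs(source$fs - stimulus$fs) > 1e-9) {
    stop("source and stimulus sampling rates differ")
  }
  if (duration_ms(source) >= epoch_ms) {
    stop("source epoch must be shorter than the FFR epoch")
  }
  train <- make_pulse_train(stimulus)
  n_out <- round(epoch_ms * source$fs / 1000)
  conv <- lin_conv(source$samples, train$samples)
  conv <- conv[seq_len(min(n_out, length(conv)))]
  if (length(conv) < n_out) conv <- c(conv, numeric(n_out - length(conv)))
  waveform(conv, fs = source$fs, t0_ms = 0)
}

#' Score a derived FFR against a measured FFR
#'
#' Cross-correlates the model-derived and measured waveforms over a +/-20 ms
#' lag window, on the common steady-state portion (default 10-110 ms) so that
#' onset transients do not dominate, and reports the maximal correlation, its
#' lag, and the squared correlation (variance explained).
#'
#' @param derived,measured [waveform]s with equal sampling rates.
#' @param max_lag_ms Lag search half-width, ms (default 20).
#' @param window Steady-state comparison window, ms (default 10-110).
#' @return A list of class `derived_ffr_fit` with `r_max`, `lag_ms`,
#'   `r_squared`.
#' @export
score_model <- function(derived, measured, max_lag_ms = 20,
                        window = c(10, 110)) {
  dseg <- waveform(derived$samples[window_indices(derived, window)],
                   derived$fs)
  mseg <- waveform(measured$samples[window_indices(measured, window)],
                   measured$fs)
  xc <- xcorr_max(dseg, mseg, max_lag_ms)
  out <- list(r_max = xc$r_max, lag_ms = xc$lag_ms, r_squared = xc$r_max^2)
  class(out) <- "derived_ffr_fit"
  out
}

#' @export
print.derived_ffr_fit <- function(x, ...) {
  cat(sprintf("<derived_ffr_fit> r = %.3f at %.2f ms lag, R^2 = %.1f%%\n",
              x$r_max, x$lag_ms, 100 * x$r_squared))
  invisible(x)
}

#' Convolution-model fit across a cohort
#'
#' For every subject: take the transient source recorded at maximal
#' ipsilateral gaze (position 5) -- by default the PAM-contaminated
#' mastoid-channel click ABR, alternatively the channel-subtraction isolated
#' PAM -- convolve it with the FFR stimulus pulse train, and cross-correlate
#' the derived FFR against the measured mastoid FFR at the same gaze
#' position. Subjects missing either recording are excluded with a warning.
#'
#' @param rec An `ffr_recordings` object containing click and FFR runs.
#' @param f0 FFR stimulus fundamental, Hz (default 100).
#' @param gaze_position Gaze position of source and measured FFR (default 5).
#' @param source `"contaminated_abr"` (default) or `"isolated_pam"`.
#' @param max_lag_ms,window Passed to [score_model()].
#' @return A list of class `cohort_model_fit`: per-subject data frame
#'   (`subject_id`, `r`, `lag_ms`, `r_squared`) plus `mean_r`, `sd_r`,
#'   `mean_r_squared`.
#' @export
cohort_model_fit <- function(rec, f0 = 100, gaze_position = 5,
                             source = c("contaminated_abr", "isolated_pam"),
                             max_lag_ms = 20, window = c(10, 110)) {
  stopifnot(inherits(rec, "ffr_recordings"))
  source <- match.arg(source)
  stim_name <- sprintf("f0_%g", f0)
  stim <- stim_spec(f0 = f0)
  rows <- list()
  for (prof in rec$cohort$subjects) {
    sid <- prof$subject_id
    mk <- sprintf("%s|click|g%d|mastoid", sid, gaze_position)
    nk <- sprintf("%s|click|g%d|neck", sid, gaze_position)
    fk <- sprintf("%s|%s|g%d|mastoid", sid, stim_name, gaze_position)
    if (is.null(rec$waves[[mk]]) || is.null(rec$waves[[fk]]) ||
        (source == "isolated_pam" && is.null(rec$waves[[nk]]))) {
      warning(sprintf("subject %s missing a required channel; treated as missing", sid))
      next
    }
    src <- if (source == "contaminated_abr") {
      bandpass_notch(rec$waves[[mk]])
    } else {
      isolate_pam(bandpass_notch(rec$waves[[mk]]), bandpass_notch(rec$waves[[nk]]))
    }
    measured <- bandpass_notch(rec$waves[[fk]])
    fit <- score_model(derive_ffr(src, stim), measured, max_lag_ms, window)
    rows[[sid]] <- data.frame(subject_id = sid, r = fit$r_max,
                              lag_ms = fit$lag_ms, r_squared = fit$r_squared,
                              stringsAsFactors = FALSE)
  }
  if (length(rows) < 2) stop("cohort_model_fit needs at least 2 subjects with complete data")
  per_subject <- do.call(rbind, rows)
  out <- list(per_subject = per_subject,
              mean_r = mean(per_subject$r), sd_r = stats::sd(per_subject$r),
              mean_r_squared = mean(per_subject$r_squared),
              source = source, f0 = f0, gaze_position = gaze_position)
  class(out) <- "cohort_model_fit"
  out
}

#' @export
print.cohort_model_fit <- function(x, ...) {
  cat(sprintf(
    "<cohort_model_fit> n = %d, mean r = %.3f (sd %.3f), mean R^2 = %.1f%% [source: %s]\n",
    nrow(x$per_subject), x$mean_r, x$sd_r, 100 * x$mean_r_squared, x$source))
  invisible(x)
}
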