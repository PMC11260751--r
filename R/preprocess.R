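#' Epoching / averaging specification
#'
#' Recording epoch windows and artifact-rejection settings. The transient
#' (ABR/click) epoch spans 0-24.7 ms and the sustained (FFR) epoch 0-127 ms;
#' sweeps containing any sample beyond +/- 50 microvolts are rejected before
#' ensemble averaging.
#'
#' @param type `"ABR"` (0-24.7 ms window) or `"FFR"` (0-127 ms window).
#' @param fs Sampling rate, Hz (default 20000).
#' @param reject_threshold_uv Absolute rejection threshold in microvolts
#'   (default 50). Use `Inf` to disable rejection.
#' @param target_sweeps Nominal number of artifact-free sweeps per condition
#'   (default 2000); metadata used by the simulator.
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(type = c("FFR", "ABR"), fs = 20000,
                       reject_threshold_uv = 50, target_sweeps = 2000) {
  type <- match.arg(type)
  window <- if (type == "ABR") c(0, 24.7) else c(0, 127)
  if (reject_threshold_uv <= 0) stop("reject_threshold_uv must be positive")
  structure(
    list(type = type, window_ms = window, fs = fs,
         reject_threshold_uv = reject_threshold_uv,
         target_sweeps = target_sweeps),
    class = "epoch_spec"
  )
}

#' Zero-phase band-pass plus notch filtering
#'
#' Applies the recording passband to a waveform: zero-phase (forward-backward)
#' 2nd-order Butterworth high-pass and low-pass sections framing the 50-3,000
#' Hz band, plus a narrow 2nd-order Butterworth band-stop centred on the
#' power-line frequency. DC is removed. Zero-phase filtering is used so that
#' latency metrics are unbiased; edges are protected by odd-reflection
#' padding before filtering.
#'
#' @param w A [waveform].
#' @param low,high Band edges in Hz (defaults 50 and 3000).
#' @param notch Notch centre frequency in Hz (default 60); `NULL` disables.
#' @param notch_bw Notch full bandwidth in Hz (default 2, i.e. Q = 30).
#' @return The filtered [waveform].
#' @examples
#' w <- waveform(sin(2 * pi * 60 * seq(0, 1, by = 5e-5)), fs = 20000)
#' f <- bandpass_notch(w)   # 60 Hz component removed
#' @export
bandpass_notch <- function(w, low = 50, high = 3000, notch = 60,
                           notch_bw = 2) {
  stopifnot(inherits(w, "waveform"))
  nyq <- w$fs / 2
  if (nyq <= high) {
    stop(sprintf("sampling rate %g Hz too low for a %g Hz band edge", w$fs, high))
  }
  x <- w$samples - mean(w$samples)
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(2, high / nyq, type = "low")
  x <- zero_phase(hp, x)
  x <- zero_phase(lp, x)
  if (!is.null(notch)) {
    bs <- signal::butter(2, c(notch - notch_bw / 2, notch + notch_bw / 2) / nyq,
                         type = "stop")
    x <- zero_phase(bs, x)
  }
  out <- w
  out$samples <- x
  out
}

# direct-form ARMA filter (equivalent to signal::filter on an Arma object,
# implemented with stats::filter for speed: MA by one-sided convolution, AR
# by the recursive filter)
arma_filter <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(numeric(nb - 1L), x), b, method = "convolution",
                     sides = 1)
  v <- v[nb:length(v)]
  if (length(a) > 1L) {
    as.numeric(stats::filter(v / a[1], -a[-1] / a[1], method = "recursive"))
  } else {
    as.numeric(v) / a[1]
  }
}

# forward-backward filtering with odd-reflection end padding so short epochs
# are not dominated by filter start-up transients
zero_phase <- function(filt, x) {
  n <- length(x)
  p <- min(n - 1L, 1000L)
  if (p >= 1L) {
    head_pad <- 2 * x[1] - x[(p + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
    x <- c(head_pad, x, tail_pad)
  }
  y <- arma_filter(filt$b, filt$a, x)
  y <- rev(arma_filter(filt$b, filt$a, rev(y)))
  if (p >= 1L) y[(p + 1L):(p + n)] else y
}

#' Sweep matrix for one subject/condition/channel
#'
#' @param epochs Numeric matrix, one row per sweep (epoch), one column per
#'   sample, in microvolts.
#' @param fs Sampling rate, Hz.
#' @param t0_ms Time of the first sample, ms.
#' @param channel `"mastoid"` (Fpz-M2) or `"neck"` (Fpz-C7).
#' @param subject_id,condition Labels carried through to averages.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(epochs, fs, t0_ms = 0, channel = c("mastoid", "neck"),
                      subject_id = NA_character_, condition = list()) {
  channel <- match.arg(channel)
  epochs <- as.matrix(epochs)
  if (nrow(epochs) < 1L) stop("sweep_set needs at least one sweep")
  if (!all(is.finite(epochs))) stop("sweep samples must all be finite")
  structure(
    list(epochs = epochs, fs = fs, t0_ms = t0_ms, channel = channel,
         subject_id = subject_id, condition = condition),
    class = "sweep_set"
  )
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d samples @ %g Hz, channel %s, subject %s\n",
              nrow(x$epochs), ncol(x$epochs), x$fs, x$channel, x$subject_id))
  invisible(x)
}

#' Amplitude-threshold rejection and ensemble averaging
#'
#' Excludes every sweep containing any sample exceeding the rejection
#' threshold in absolute value (the criterion is applied to the raw,
#' unfiltered sweep, mirroring online hardware rejection), then takes the
#' arithmetic mean of the surviving sweeps.
#'
#' @param sweeps A [sweep_set].
#' @param spec An [epoch_spec] supplying the rejection threshold.
#' @return An `averaged_response`: a [waveform] with additional fields
#'   `n_sweeps_used`, `n_sweeps_input`, `channel`, `subject_id`, `condition`.
#' @examples
#' m <- matrix(rnorm(20 * 100), nrow = 20)
#' avg <- reject_and_average(sweep_set(m, fs = 20000, channel = "neck"),
#'                           epoch_spec("ABR"))
#' avg$n_sweeps_used
#' @export
reject_and_average <- function(sweeps, spec = epoch_spec()) {
  stopifnot(inherits(sweeps, "sweep_set"), inherits(spec, "epoch_spec"))
  thr <- spec$reject_threshold_uv
  keep <- apply(abs(sweeps$epochs), 1L, max) <= thr
  if (!any(keep)) {
    stop(sprintf("all %d sweeps exceed the +/-%g uV rejection threshold",
                 nrow(sweeps$epochs), thr))
  }
  avg <- colMeans(sweeps$epochs[keep, , drop = FALSE])
  out <- waveform(avg, fs = sweeps$fs, t0_ms = sweeps$t0_ms)
  out$n_sweeps_used <- sum(keep)
  out$n_sweeps_input <- nrow(sweeps$epochs)
  out$channel <- sweeps$channel
  out$subject_id <- sweeps$subject_id
  out$condition <- sweeps$condition
  class(out) <- c("averaged_response", class(out))
  out
}

#' Isolate the PAM artifact by channel subtraction
#'
#' Sample-wise difference of the mastoid- and neck-referenced averages of the
#' same subject and condition. The postauricular-muscle artifact projects
#' onto the mastoid reference but not the distal neck (C7) reference, so the
#' difference waveform isolates it; neurogenic ABR components common to both
#' channels cancel.
#'
#' @param mastoid,neck `averaged_response` (or plain [waveform]) objects on
#'   identical time grids.
#' @return A [waveform] holding the difference (mastoid minus neck).
#' @export
isolate_pam <- function(mastoid, neck) {
  check_same_grid(mastoid, neck)
  chans <- c(mastoid$channel, neck$channel)
  if (!is.null(mastoid$channel) && !is.null(neck$channel) &&
      !identical(chans, c("mastoid", "neck"))) {
    stop("isolate_pam expects (mastoid, neck) channel order")
  }
  if (!is.null(mastoid$subject_id) && !is.null(neck$subject_id) &&
      !identical(mastoid$subject_id, neck$subject_id)) {
    stop("isolate_pam inputs come from different subjects")
  }
  waveform(mastoid$samples - neck$samples, fs = mastoid$fs,
           t0_ms = mastoid$t0_ms)
}
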