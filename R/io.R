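# Canonical interchange dialect: dot-decimal CSV with '#'-prefixed metadata
# headers. Times in ms, voltages in uV, frequencies in Hz throughout.

#' Write a waveform to delimited text
#'
#' Two columns (`time_ms`, `amplitude`) preceded by `#`-prefixed header lines
#' carrying the sampling metadata. Round-trips losslessly to at least 12
#' significant digits via [read_waveform_csv()].
#'
#' @param w A [waveform].
#' @param path Output file path.
#' @param units Unit label stored in the header (default `"uV"`).
#' @param extra Named character vector of additional header fields.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path, units = "uV", extra = NULL) {
  stopifnot(inherits(w, "waveform"))
  header <- c(
    sprintf("# fs=%.12g", w$fs),
    sprintf("# t0_ms=%.12g", w$t0_ms),
    sprintf("# units=%s", units)
  )
  if (!is.null(extra)) {
    header <- c(header, sprintf("# %s=%s", names(extra), as.character(extra)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines("time_ms,amplitude", con)
  writeLines(sprintf("%.12g,%.15g", time_axis_ms(w), w$samples), con)
  invisible(path)
}

#' Read a waveform from delimited text
#'
#' Parses the dialect written by [write_waveform_csv()]. The header must
#' declare `fs` and `t0_ms`; the numeric dialect is dot-decimal (files using
#' a comma decimal separator are rejected).
#'
#' @param path Input file path.
#' @return A [waveform] with attribute `"units"`.
#' @export
read_waveform_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  missing <- setdiff(c("fs", "t0_ms"), names(meta))
  if (length(missing) > 0) {
    stop(sprintf("waveform file is missing header field(s): %s",
                 paste(missing, collapse = ", ")))
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2) stop("waveform file has no data rows")
  if (any(grepl(";", body, fixed = TRUE))) {
    stop("file appears to use a semicolon/comma-decimal dialect; this reader requires dot-decimal CSV")
  }
  fields <- strsplit(body[-1], ",", fixed = TRUE)
  if (any(lengths(fields) != 2)) {
    stop("malformed data rows: expected exactly two dot-decimal columns; comma-decimal files are not supported")
  }
  amp <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  if (any(is.na(amp))) stop("non-numeric amplitude values; the dialect is dot-decimal CSV")
  w <- waveform(amp, fs = as.numeric(meta$fs), t0_ms = as.numeric(meta$t0_ms))
  attr(w, "units") <- meta$units %||% "uV"
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline run configuration
#'
#' Bundles every parameter of a full simulate -> preprocess -> metrics ->
#' model -> stats run. Every stochastic stage draws from the single `seed`;
#' a configuration without a seed is refused.
#'
#' @param n_subjects Cohort size (default 20).
#' @param seed Integer seed (mandatory).
#' @param f0s FFR stimulus fundamentals, Hz.
#' @param n_sweeps Sweeps per condition.
#' @param structure An [effect_structure].
#' @param mode Simulation mode, `"average"` or `"sweeps"`.
#' @param ffr_window,pam_window,onset_window,max_lag_ms Analysis windows (ms).
#' @param n_boot Mediation bootstrap resamples.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_subjects = 20, seed = NULL, f0s = 100,
                       n_sweeps = 2000, structure = effect_structure(),
                       mode = "average", ffr_window = c(10, 110),
                       pam_window = c(8, 18), onset_window = c(6, 12),
                       max_lag_ms = 20, n_boot = 1000) {
  if (is.null(seed)) stop("run_config requires an explicit integer seed")
  stopifnot(inherits(structure, "effect_structure"))
  windows <- list(ffr = ffr_window, pam = pam_window, onset = onset_window)
  for (wname in names(windows)) {
    wv <- windows[[wname]]
    if (wv[1] < 0 || wv[2] > FFR_EPOCH_MS) {
      stop(sprintf("%s window must lie within the recording epochs", wname))
    }
  }
  out <- list(n_subjects = n_subjects, seed = as.integer(seed), f0s = f0s,
              n_sweeps = n_sweeps, structure = structure, mode = mode,
              ffr_window = ffr_window, pam_window = pam_window,
              onset_window = onset_window, max_lag_ms = max_lag_ms,
              n_boot = n_boot)
  class(out) <- "run_config"
  out
}

#' Run the full analysis pipeline
#'
#' simulate -> measure -> convolution model -> statistics, returning every
#' intermediate product. When `out_dir` is given, the metrics table, model
#' fit, statistical results and a manifest (parameters, seeds, file digests)
#' are also written as delimited text; re-running the same configuration
#' reproduces all numeric outputs bit-identically.
#'
#' @param config A [run_config].
#' @param out_dir Optional output directory.
#' @return A list of class `pipeline_result` with elements `cohort`,
#'   `recordings`, `metrics`, `model_fit`, `contrasts`, `correlation_gaze5`,
#'   `partials`, `regression`, `mediation`, and `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- sample_cohort(config$n_subjects, config$structure,
                          seed = config$seed)
  rec <- simulate_recordings(cohort, f0s = config$f0s,
                             n_sweeps = config$n_sweeps, mode = config$mode,
                             seed = config$seed + 500000L)
  metrics <- metrics_table(rec, pam_window = config$pam_window,
                           ffr_window = config$ffr_window,
                           onset_window = config$onset_window)
  f0 <- config$f0s[1]
  mast <- metrics[metrics$channel == "mastoid" & metrics$f0 == f0, ]
  g5 <- mast[mast$gaze_position == 5, ]
  agg <- aggregated_table(metrics, channel = "mastoid", f0 = f0)
  model_fit <- cohort_model_fit(rec, f0 = f0, max_lag_ms = config$max_lag_ms,
                                window = config$ffr_window)
  contrasts <- rbind(gaze_contrasts(metrics, "mastoid", f0),
                     gaze_contrasts(metrics, "neck", f0))
  result <- list(
    cohort = cohort, recordings = rec, metrics = metrics,
    model_fit = model_fit, contrasts = contrasts,
    correlation_gaze5 = correlate(g5, "pam_p2p", "ffr_rms"),
    correlation_music = correlate(agg, "music_years", "ffr_rms"),
    partials = list(
      pam_given_music = partial_correlation(agg, "pam_p2p", "ffr_rms", "music_years"),
      music_given_pam = partial_correlation(agg, "music_years", "ffr_rms", "pam_p2p")
    ),
    regression = fit_regression(agg),
    mediation = mediate(agg, n_boot = config$n_boot,
                        seed = config$seed + 900000L),
    config = config
  )
  class(result) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  utils::write.csv(result$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$model_fit$per_subject,
                   file.path(out_dir, "model_fit.csv"), row.names = FALSE)
  utils::write.csv(result$contrasts, file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE)
  med <- result$mediation
  summary_lines <- c(
    sprintf("n_subjects=%d", cfg$n_subjects),
    sprintf("seed=%d", cfg$seed),
    sprintf("n_sweeps=%d", cfg$n_sweeps),
    sprintf("mode=%s", cfg$mode),
    sprintf("mean_r_xcorr=%.6f", result$model_fit$mean_r),
    sprintf("mean_r_squared=%.6f", result$model_fit$mean_r_squared),
    sprintf("r_pam_ffr_gaze5=%.6f", result$correlation_gaze5$r),
    sprintf("partial_pam_ffr_given_music=%.6f", result$partials$pam_given_music$r),
    sprintf("partial_music_ffr_given_pam=%.6f", result$partials$music_given_pam$r),
    sprintf("max_vif=%.6f", max(result$regression$vif)),
    sprintf("sobel_z=%.6f", med$sobel_z),
    sprintf("sobel_p=%.6g", med$sobel_p),
    sprintf("boot_ci=[%.6f, %.6f]", med$boot_ci[1], med$boot_ci[2])
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  files <- c("metrics.csv", "model_fit.csv", "contrasts.csv", "summary.txt")
  digests <- tools::md5sum(file.path(out_dir, files))
  manifest <- c(
    sprintf("package_version=%s", as.character(utils::packageVersion("pamffr"))),
    summary_lines[1:4],
    sprintf("md5_%s=%s", basename(names(digests)), unname(digests))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$model_fit)
  cat(sprintf("  r(PAM, FFR) at gaze 5 = %.3f\n", x$correlation_gaze5$r))
  print(x$mediation)
  invisible(x)
}
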