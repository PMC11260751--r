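#' Square-root transform of amplitude columns
#'
#' Applies an element-wise square root to the amplitude columns of a metrics
#' table (to improve normality / homogeneity of variance before parametric
#' analysis); latency columns are untouched.
#'
#' @param table A [metrics_table()] data frame.
#' @param columns Amplitude columns to transform.
#' @return The transformed table.
#' @export
sqrt_transform <- function(table,
                           columns = c("pam_p2p", "ffr_rms", "f0_amp",
                                       "h2_amp", "h3_amp")) {
  columns <- intersect(columns, names(table))
  for (col in columns) {
    x <- table[[col]]
    if (any(x < 0, na.rm = TRUE)) {
      stop(sprintf("column %s contains negative amplitudes", col))
    }
    table[[col]] <- sqrt(x)
  }
  table
}

#' Orthogonal polynomial contrast weights for the gaze angles
#'
#' Linear and quadratic orthogonal polynomial weights computed for the actual
#' (unequally spaced) gaze angles via Gram-Schmidt on (1, theta, theta^2).
#' Weights are orthogonal, sum to zero, and have unit norm.
#'
#' @param angles Gaze angles in degrees (default -70, -35, 0, +35, +70).
#' @return A matrix with columns `linear` and `quadratic`.
#' @export
gaze_contrast_weights <- function(angles = GAZE_ANGLES) {
  w <- stats::poly(angles, degree = 2)
  colnames(w) <- c("linear", "quadratic")
  w[, , drop = FALSE]
}

#' Within-subject polynomial gaze contrasts
#'
#' Tests the shape of the gaze dependence of FFR amplitude for one channel:
#' per-subject linear and quadratic contrast scores over the five gaze
#' positions, followed by a one-sample t-test of the scores across subjects
#' (df = n_subjects - 1). A U-shaped (midline-minimum) gaze profile loads on
#' the quadratic contrast.
#'
#' @param table A [metrics_table()] data frame.
#' @param channel Channel to analyse (`"mastoid"` or `"neck"`).
#' @param f0 Stimulus F0 rows to use (default 100).
#' @param value_col Response column (default `"ffr_rms"`).
#' @return A data frame of class `contrast_result` with one row per contrast:
#'   `contrast`, `estimate`, `t_statistic`, `df`, `p_value`, `channel`.
#'   Subjects missing any gaze cell are dropped with a warning.
#' @export
gaze_contrasts <- function(table, channel = "mastoid", f0 = 100,
                           value_col = "ffr_rms") {
  sub <- table[table$channel == channel & table$f0 == f0, ]
  wide <- stats::reshape(
    sub[, c("subject_id", "gaze_position", value_col)],
    idvar = "subject_id", timevar = "gaze_position", direction = "wide"
  )
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    warning(sprintf("%d subject(s) dropped: missing gaze cells", sum(!complete)))
    wide <- wide[complete, ]
  }
  if (nrow(wide) < 2) stop("gaze_contrasts needs at least 2 complete subjects")
  y <- as.matrix(wide[, -1])
  # order columns by gaze position
  ord <- order(as.integer(sub("^.*\\.", "", colnames(y))))
  y <- y[, ord, drop = FALSE]
  w <- gaze_contrast_weights(GAZE_ANGLES[as.integer(sub("^.*\\.", "", colnames(y)))])
  out <- do.call(rbind, lapply(c("linear", "quadratic"), function(k) {
    scores <- as.numeric(y %*% w[, k])
    tt <- stats::t.test(scores)
    data.frame(contrast = k, estimate = mean(scores),
               t_statistic = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, channel = channel,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("contrast_result", class(out))
  out
}

#' Pearson correlation between two table columns
#'
#' @param table A data frame.
#' @param x_col,y_col Column names.
#' @return A list with `r`, `p` (two-sided t-based), `n`, `df`.
#' @export
correlate <- function(table, x_col, y_col) {
  ok <- stats::complete.cases(table[, c(x_col, y_col)])
  x <- table[[x_col]][ok]; y <- table[[y_col]][ok]
  if (length(x) < 3) stop("correlate needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlate undefined for zero-variance input")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}

#' Partial correlation controlling for a third variable
#'
#' Correlation of the least-squares residuals of `x_col` and `y_col` after
#' regressing each on `control_col`; two-sided p from a t-statistic with
#' df = n - 3.
#'
#' @param table A data frame.
#' @param x_col,y_col,control_col Column names.
#' @return A list with `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(table, x_col, y_col, control_col) {
  ok <- stats::complete.cases(table[, c(x_col, y_col, control_col)])
  x <- table[[x_col]][ok]; y <- table[[y_col]][ok]
  z <- table[[control_col]][ok]
  n <- length(x)
  if (n < 4) stop("partial_correlation needs at least 4 complete triples")
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("partial correlation undefined: zero residual variance")
  }
  r <- stats::cor(rx, ry)
  df <- n - 3
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), n = n, df = df)
}

#' FFR regression on music training and PAM amplitude
#'
#' Ordinary least squares of the FFR measure on musical training, PAM
#' amplitude and their interaction, with variance inflation factors for the
#' main-effect predictors, partial correlations of each predictor with the
#' response (controlling the other), and a nested-model F-test of the
#' interaction model against the music-only model.
#'
#' @param table A data frame with complete rows for the three columns.
#' @param y_col,music_col,pam_col Column names.
#' @return A list of class `regression_fit`: `model` (the `lm` fit),
#'   `coefficients`, `vif` (named, music and PAM), `partial_r`,
#'   `f_test` (F, df1, df2, p for interaction vs music-only).
#' @export
fit_regression <- function(table, y_col = "ffr_rms", music_col = "music_years",
                           pam_col = "pam_p2p") {
  ok <- stats::complete.cases(table[, c(y_col, music_col, pam_col)])
  d <- data.frame(y = table[[y_col]][ok], music = table[[music_col]][ok],
                  pam = table[[pam_col]][ok])
  if (nrow(d) < 5) stop("fit_regression needs at least 5 complete rows")
  if (stats::sd(d$music) == 0 || stats::sd(d$pam) == 0) {
    stop("rank deficiency: a predictor column has zero variance")
  }
  r_mp <- stats::cor(d$music, d$pam)
  if (abs(r_mp) > 1 - 1e-10) {
    stop("rank deficiency: music and pam columns are collinear")
  }
  full <- stats::lm(y ~ music * pam, data = d)
  base_m <- stats::lm(y ~ music, data = d)
  ftab <- stats::anova(base_m, full)
  vif <- c(music = 1 / (1 - r_mp^2), pam = 1 / (1 - r_mp^2))
  pr <- list(
    music = partial_correlation(d, "music", "y", "pam"),
    pam = partial_correlation(d, "pam", "y", "music")
  )
  out <- list(model = full, coefficients = summary(full)$coefficients,
              vif = vif, partial_r = pr,
              f_test = list(F = ftab$F[2], df1 = ftab$Df[2],
                            df2 = ftab$Res.Df[2], p = ftab$`Pr(>F)`[2]),
              n = nrow(d))
  class(out) <- "regression_fit"
  out
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> n = %d, VIF = %.2f, interaction-model F(%d, %d) = %.2f (p = %.3g)\n",
              x$n, max(x$vif), x$f_test$df1, x$f_test$df2, x$f_test$F,
              x$f_test$p))
  invisible(x)
}

# fast OLS paths a, b, c, c' with classical standard errors for a and b
mediation_paths <- function(x, m, y) {
  n <- length(x)
  fit_a <- stats::lm.fit(cbind(1, x), m)
  a <- fit_a$coefficients[2]
  s2a <- sum(fit_a$residuals^2) / (n - 2)
  se_a <- sqrt(s2a / sum((x - mean(x))^2))
  Xb <- cbind(1, x, m)
  fit_b <- stats::lm.fit(Xb, y)
  b <- fit_b$coefficients[3]
  cprime <- fit_b$coefficients[2]
  s2b <- sum(fit_b$residuals^2) / (n - 3)
  XtXinv <- chol2inv(chol(crossprod(Xb)))
  se_b <- sqrt(s2b * XtXinv[3, 3])
  se_cprime <- sqrt(s2b * XtXinv[2, 2])
  fit_c <- stats::lm.fit(cbind(1, x), y)
  cc <- fit_c$coefficients[2]
  s2c <- sum(fit_c$residuals^2) / (n - 2)
  se_c <- sqrt(s2c / sum((x - mean(x))^2))
  list(a = unname(a), se_a = se_a, b = unname(b), se_b = se_b,
       c = unname(cc), se_c = se_c, cprime = unname(cprime),
       se_cprime = se_cprime, n = n)
}

#' Bootstrap Sobel mediation analysis
#'
#' Tests whether a mediator M carries the relation between X and Y
#' (X -> M -> Y). Paths are ordinary least squares: `a` (X -> M), `b`
#' (M -> Y controlling X), `c` (total X -> Y), `c'` (direct X -> Y
#' controlling M); the OLS identity `c = c' + a b` holds exactly. The
#' indirect effect `a b` is tested with the Sobel statistic
#' `z = a b / sqrt(b^2 se_a^2 + a^2 se_b^2)` (normal two-sided p) and with a
#' percentile bootstrap confidence interval over case resamples. The
#' classical mediation criteria are flagged: (i) X predicts Y, (ii) X
#' predicts M, (iii) the direct X -> Y path loses significance after
#' controlling M (full mediation; if it stays significant while the indirect
#' effect is reliable, mediation is partial).
#'
#' @param table A data frame.
#' @param x_col,m_col,y_col Predictor, mediator and outcome columns
#'   (defaults: music years, PAM peak-to-peak, FFR RMS).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level of the percentile interval.
#' @param alpha Significance level for the criteria flags.
#' @return A list of class `mediation_result` with `paths`, `sobel_z`,
#'   `sobel_p`, `boot_ci`, `n_boot`, `criteria` (logical flags i-iii and
#'   `partial_mediation`), `n`.
#' @export
mediate <- function(table, x_col = "music_years", m_col = "pam_p2p",
                    y_col = "ffr_rms", n_boot = 1000, seed = 1L,
                    conf_level = 0.95, alpha = 0.05) {
  ok <- stats::complete.cases(table[, c(x_col, m_col, y_col)])
  x <- table[[x_col]][ok]; m <- table[[m_col]][ok]; y <- table[[y_col]][ok]
  n <- length(x)
  if (n < 10) stop("mediate needs at least 10 complete triples")
  if (stats::sd(m) == 0) stop("mediate undefined for a zero-variance mediator")
  p <- mediation_paths(x, m, y)
  sobel_z <- (p$a * p$b) / sqrt(p$b^2 * p$se_a^2 + p$a^2 * p$se_b^2)
  sobel_p <- 2 * stats::pnorm(-abs(sobel_z))
  boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(m[idx]) == 0) return(NA_real_)
      pb <- mediation_paths(x[idx], m[idx], y[idx])
      pb$a * pb$b
    }, numeric(1))
  })
  boot <- boot[!is.na(boot)]
  qs <- stats::quantile(boot, c((1 - conf_level) / 2, (1 + conf_level) / 2),
                        names = FALSE)
  p_c <- 2 * stats::pt(-abs(p$c / p$se_c), n - 2)
  p_a <- 2 * stats::pt(-abs(p$a / p$se_a), n - 2)
  p_cprime <- 2 * stats::pt(-abs(p$cprime / p$se_cprime), n - 3)
  criteria <- list(
    i_x_predicts_y = p_c < alpha,
    ii_x_predicts_m = p_a < alpha,
    iii_direct_loses_significance = p_cprime >= alpha,
    partial_mediation = (p_cprime < alpha) && (sobel_p < alpha)
  )
  out <- list(paths = p, sobel_z = unname(sobel_z), sobel_p = unname(sobel_p),
              boot_ci = qs, n_boot = length(boot), criteria = criteria,
              p_values = list(c = p_c, a = p_a, cprime = p_cprime), n = n)
  class(out) <- "mediation_result"
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation_result> n = %d: a = %.4f, b = %.4f, c = %.4f, c' = %.4f\n  Sobel z = %.2f (p = %.3g), %d-resample 95%% CI of a*b: [%.4f, %.4f]\n",
    x$n, x$paths$a, x$paths$b, x$paths$c, x$paths$cprime,
    x$sobel_z, x$sobel_p, x$n_boot, x$boot_ci[1], x$boot_ci[2]))
  invisible(x)
}
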