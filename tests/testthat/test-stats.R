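make_table <- function(y_by_gaze, n_subj = 12, noise = 0.1, seed = 1,
                       channel = "mastoid") {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_subj), function(i) {
      data.frame(subject_id = sprintf("s%02d", i), gaze_position = 1:5,
                 channel = channel, f0 = 100,
                 ffr_rms = y_by_gaze + rnorm(5, 0, noise))
    }))
  })
}

test_that("sqrt transform acts element-wise on amplitude columns only", {
  tb <- data.frame(pam_p2p = c(4, 0, 2.25), ffr_rms = c(1, 9, 16),
                   pam_latency = c(13, 14, 15))
  out <- sqrt_transform(tb)
  expect_equal(out$pam_p2p, c(2, 0, 1.5))
  expect_equal(out$ffr_rms, c(1, 3, 4))
  expect_equal(out$pam_latency, tb$pam_latency)
  expect_equal(sqrt_transform(out)$ffr_rms, tb$ffr_rms^0.25)
  expect_equal(order(out$ffr_rms), order(tb$ffr_rms))
  expect_error(sqrt_transform(data.frame(ffr_rms = -1)), "negative")
})

test_that("gaze contrast weights are orthogonal and sum to zero", {
  w <- gaze_contrast_weights()
  expect_equal(colSums(w), c(linear = 0, quadratic = 0), tolerance = 1e-12)
  expect_equal(sum(w[, 1] * w[, 2]), 0, tolerance = 1e-12)
  expect_equal(colSums(w^2), c(linear = 1, quadratic = 1), tolerance = 1e-12)
})

test_that("a flat gaze profile yields null contrasts with uniform p-values", {
  ps <- sapply(1:40, function(s) {
    tb <- make_table(rep(1, 5), noise = 0.2, seed = s)
    cr <- gaze_contrasts(tb)
    cr$p_value[cr$contrast == "quadratic"]
  })
  expect_gt(mean(ps), 0.3)                # roughly uniform, not piled at 0
  expect_lt(mean(ps), 0.7)
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("a planted U-shaped gaze profile loads on the quadratic contrast", {
  g <- gaze_gain(c(-70, -35, 0, 35, 70), effect_structure())
  tb <- make_table(g, n_subj = 20, noise = 0.05, seed = 2)
  cr <- gaze_contrasts(tb)
  expect_lt(cr$p_value[cr$contrast == "quadratic"], 0.01)
  expect_equal(cr$df, c(19, 19))
  # flat-channel tables stay non-significant in the vast majority of seeds
  frac_ns <- mean(sapply(1:30, function(s) {
    tb0 <- make_table(rep(1, 5), noise = 0.2, seed = 100 + s, channel = "neck")
    all(gaze_contrasts(tb0, channel = "neck")$p_value > 0.05)
  }))
  expect_gte(frac_ns, 0.8)
})

test_that("subjects with missing gaze cells are dropped with a warning", {
  tb <- make_table(rep(1, 5), n_subj = 5)
  tb <- tb[-3, ]                          # s01 loses gaze position 3
  expect_warning(cr <- gaze_contrasts(tb), "dropped")
})

test_that("correlate matches closed-form cases", {
  tb <- data.frame(x = 1:20, y = 1:20 * 2 + 3)
  expect_equal(correlate(tb, "x", "y")$r, 1)
  expect_error(correlate(data.frame(x = rep(1, 5), y = 1:5), "x", "y"),
               "zero-variance")
  expect_error(correlate(data.frame(x = 1:2, y = 1:2), "x", "y"),
               "at least 3")
})

test_that("partial correlation agrees with two independent formulas", {
  set.seed(8)
  for (rep in 1:20) {
    n <- 50
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + 0.4 * x + rnorm(n)
    tb <- data.frame(x = x, y = y, z = z)
    got <- partial_correlation(tb, "x", "y", "z")
    # oracle 1: inverse correlation matrix
    P <- solve(stats::cor(cbind(x, y, z)))
    r1 <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    # oracle 2: closed-form from pairwise correlations
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    r2 <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(got$r, r1, tolerance = 1e-10)
    expect_equal(got$r, r2, tolerance = 1e-10)
    expect_equal(got$df, n - 3)
  }
})

test_that("partial correlation handles degenerate control structure", {
  set.seed(9)
  n <- 2000
  x <- rnorm(n); y <- 0.5 * x + rnorm(n); z <- rnorm(n)   # z independent
  tb <- data.frame(x = x, y = y, z = z)
  expect_equal(partial_correlation(tb, "x", "y", "z")$r,
               correlate(tb, "x", "y")$r, tolerance = 0.02)
  # y (nearly) equal to the control carries no partial information
  tb2 <- data.frame(x = x, y = z + rnorm(n, 0, 1e-6), z = z)
  expect_lt(abs(partial_correlation(tb2, "x", "y", "z")$r), 0.05)
})

test_that("regression reports VIFs, partial correlations and the F-test", {
  set.seed(10)
  n <- 200
  music <- rnorm(n)
  pam <- residuals(lm(rnorm(n) ~ music))    # exactly orthogonal predictor
  y <- 0.5 * music + 0.8 * pam + rnorm(n)
  tb <- data.frame(ffr_rms = y, music_years = music, pam_p2p = pam)
  fit <- fit_regression(tb)
  expect_equal(unname(fit$vif["music"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$vif["pam"]), 1 / (1 - cor(music, pam)^2))
  expect_gt(fit$f_test$F, 10)               # pam terms add real information
  expect_equal(fit$f_test$df1, 2L)          # pam + interaction vs music-only

  # no planted PAM path: its coefficient is null on average
  coefs <- sapply(1:10, function(s) {
    withr::with_seed(s, {
      music <- rnorm(300); pam <- rnorm(300)
      y <- 0.6 * music + rnorm(300)
      fit_regression(data.frame(ffr_rms = y, music_years = music,
                                pam_p2p = pam))$coefficients["pam", 1]
    })
  })
  expect_lt(abs(mean(coefs)), 0.05)

  expect_error(fit_regression(data.frame(ffr_rms = rnorm(20),
                                         music_years = 1:20,
                                         pam_p2p = (1:20) * 2)),
               "collinear")
})

test_that("mediation paths satisfy the OLS identity and match closed forms", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 60
    x <- rnorm(n); m <- 0.5 * x + rnorm(n); y <- 0.4 * m + 0.2 * x + rnorm(n)
    med <- mediate(data.frame(music_years = x, pam_p2p = m, ffr_rms = y),
                   n_boot = 50, seed = rep)
    p <- med$paths
    expect_equal(p$c, p$cprime + p$a * p$b, tolerance = 1e-10)
  }

  # large-sample Sobel z against the analytic value with known paths
  set.seed(12)
  n <- 5000; a <- 0.5; b <- 0.4
  x <- rnorm(n)
  m <- a * x + sqrt(1 - a^2) * rnorm(n)
  y <- b * m + 0.2 * x + rnorm(n)
  med <- mediate(data.frame(music_years = x, pam_p2p = m, ffr_rms = y),
                 n_boot = 50, seed = 1)
  se_a <- sqrt((1 - a^2) / n)
  s2y <- 1                                   # residual variance of y
  # var of b-hat in y ~ x + m: s2y / (n * (1 - a^2)) for standardized x, m
  se_b <- sqrt(s2y / (n * (1 - cor(x, m)^2) * var(m)))
  z_analytic <- (a * b) / sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  expect_equal(med$sobel_z, z_analytic, tolerance = 0.1)

  # planted null indirect path: z near zero, CI covers zero
  zs <- sapply(1:10, function(s) {
    withr::with_seed(s, {
      x <- rnorm(100); m <- rnorm(100); y <- 0.5 * m + rnorm(100)
      med0 <- mediate(data.frame(music_years = x, pam_p2p = m, ffr_rms = y),
                      n_boot = 200, seed = s)
      c(med0$sobel_z, med0$boot_ci)
    })
  })
  expect_lt(abs(mean(zs[1, ])), 0.6)
  expect_gt(mean(zs[2, ] <= 0 & zs[3, ] >= 0), 0.7)

  expect_error(mediate(data.frame(music_years = rnorm(20),
                                  pam_p2p = rep(1, 20),
                                  ffr_rms = rnorm(20))),
               "zero-variance")
})

test_that("the bootstrap percentile CI has nominal coverage under the null", {
  # 500 independent null coh-level datasets (no X -> M path): the 95% CI of
  # the indirect effect should exclude zero in about 5% of runs
  excl <- sapply(1:500, function(s) {
    withr::with_seed(1000 + s, {
      n <- 100
      x <- rnorm(n)
      m <- rnorm(n)                         # a = 0
      y <- 0.5 * m + 0.3 * x + rnorm(n)
      med <- mediate(data.frame(music_years = x, pam_p2p = m, ffr_rms = y),
                     n_boot = 500, seed = s)
      med$boot_ci[1] > 0 || med$boot_ci[2] < 0
    })
  })
  expect_gte(mean(excl), 0.03)
  expect_lte(mean(excl), 0.07)
})
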