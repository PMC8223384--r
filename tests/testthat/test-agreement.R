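test_that("Spearman correlation respects rank invariance and handles ties", {
  x <- c(3, 7, 12, 20, 45)
  expect_equal(spearman_with_ci(x, exp(x / 10))$rho, 1)
  expect_equal(spearman_with_ci(x, -log(x))$rho, -1)

  tie <- spearman_with_ci(c(1, 2, 3, 4), c(1, 2, 2, 4))
  expect_equal(round(tie$rho, 4), 0.9487)
  expect_equal(tie$rho, oracle_spearman(c(1, 2, 3, 4), c(1, 2, 2, 4)),
               tolerance = 1e-12)

  expect_error(spearman_with_ci(rep(1, 5), 1:5), "constant")
  # Fisher-z CI brackets the estimate and narrows with n
  withr::with_seed(1, { x2 <- rnorm(30); y2 <- x2 + rnorm(30) })
  s <- spearman_with_ci(x2, y2)
  expect_true(s$ci[1] < s$rho && s$rho < s$ci[2])
  expect_true(s$p_value < 0.05)
})

test_that("OLS recovers an exact linear relation and flags no outliers", {
  x <- c(0, 1000, 2000, 3000)
  y <- 192.4 + 0.31 * x
  fit <- ols_with_outliers(x, y)
  expect_equal(fit$intercept, 192.4, tolerance = 1e-9)
  expect_equal(fit$slope, 0.31, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_length(fit$outliers, 0)
  expect_true(all(fit$std_residuals == 0))
})

test_that("a grossly displaced point is the one flagged at cutoff 3", {
  withr::with_seed(10, {
    x <- seq(0, 19)
    y <- 2 + 0.5 * x + rnorm(20, sd = 0.1)
  })
  x <- c(x, 10); y <- c(y, 2 + 0.5 * 10 + 10 * 0.1 * 10)  # displaced by 10x scatter
  fit <- ols_with_outliers(x, y, cutoff = 3)
  expect_identical(fit$outliers, 21L)
  expect_false(is.null(fit$fit_excluding_outliers))
  expect_equal(fit$fit_excluding_outliers$slope, 0.5, tolerance = 0.05)
  expect_error(ols_with_outliers(rep(2, 5), 1:5), "zero variance")
})

test_that("Bland-Altman handles constant differences and the hand oracle", {
  x <- c(10, 20, 30, 40)
  ba_const <- bland_altman(x, x + 5)
  expect_equal(ba_const$bias, 5)
  expect_equal(ba_const$crude_loa, c(5, 5))
  expect_equal(ba_const$bias_slope, 0)
  expect_equal(ba_const$residual_sd, 0)

  # d = (-2, 0, 2) with means uncorrelated with d -> crude LOA +/- 3.92
  m <- c(1, 5, 1); d <- c(-2, 0, 2)
  ba <- bland_altman(m - d / 2, m + d / 2)
  expect_equal(ba$bias, 0)
  expect_equal(ba$crude_loa, c(-3.92, 3.92))
  expect_equal(ba$bias_slope, 0)
})

test_that("noiseless proportional bias d = 267.4 - 1.0 m is recovered exactly", {
  m <- c(0, 100, 250, 400, 600, 900)
  d <- 267.4 - 1.0 * m
  ba <- bland_altman(m - d / 2, m + d / 2)
  expect_equal(ba$bias_intercept, 267.4, tolerance = 1e-9)
  expect_equal(ba$bias_slope, -1.0, tolerance = 1e-12)
  expect_equal(ba$residual_sd, 0, tolerance = 1e-9)
})

test_that("zero-slope bias model reduces regression LOA to the documented ratio", {
  # construct differences exactly orthogonal to means
  m <- c(1, 2, 3, 4, 5, 6)
  d <- c(1, -1, 0, 0, -1, 1)
  stopifnot(abs(sum((m - mean(m)) * (d - mean(d)))) < 1e-12)
  ba <- bland_altman(m - d / 2, m + d / 2)
  expect_equal(ba$bias_slope, 0, tolerance = 1e-12)
  n <- length(d)
  expect_equal(ba$residual_sd, ba$sd_diff * sqrt((n - 1) / (n - 2)),
               tolerance = 1e-10)
  expect_equal(ba$bias_intercept, ba$bias, tolerance = 1e-12)
})

test_that("ICC matches the hand variance-components fixture", {
  m <- matrix(c(1, 3, 5, 2, 4, 6), ncol = 2)  # columns offset by 1
  icc <- icc_single_2way_mixed(m)
  expect_equal(icc$mean_squares[["MSR"]], 8)
  expect_equal(icc$mean_squares[["MSC"]], 1.5)
  expect_equal(icc$mean_squares[["MSE"]], 0)
  expect_equal(icc$consistency$value, 1)
  expect_equal(icc$absolute$value, 8 / 9, tolerance = 1e-12)

  ident <- icc_single_2way_mixed(cbind(c(2, 9, 4), c(2, 9, 4)))
  expect_equal(ident$consistency$value, 1)
  expect_equal(ident$absolute$value, 1)
})

test_that("independent equal-variance columns give ICC near zero", {
  withr::with_seed(6, m <- matrix(rnorm(2000), ncol = 2))
  icc <- icc_single_2way_mixed(m)
  se <- 1 / sqrt(nrow(m))   # Monte-Carlo scale for a correlation-like quantity
  expect_lt(abs(icc$consistency$value), 3 * se)
  expect_lt(abs(icc$absolute$value), 3 * se)
  expect_true(icc$consistency$ci[1] < icc$consistency$value &&
                icc$consistency$value < icc$consistency$ci[2])
})

test_that("consistency ICC >= absolute ICC whenever raters differ systematically", {
  withr::with_seed(12, {
    for (rep in 1:10) {
      subj <- rnorm(15)
      m <- cbind(subj + rnorm(15, sd = 0.3), subj + 1.5 + rnorm(15, sd = 0.3))
      icc <- icc_single_2way_mixed(m)
      if (icc$mean_squares[["MSC"]] > icc$mean_squares[["MSE"]])
        expect_gte(icc$consistency$value, icc$absolute$value)
    }
  })
})

test_that("ICC validates its input table", {
  expect_error(icc_single_2way_mixed(matrix(c(1, 2, NA, 4, 5, 6), ncol = 2)),
               "incomplete")
  expect_error(icc_single_2way_mixed(matrix(1:4, ncol = 2)), "at least 3")
})

test_that("weighted kappa reproduces the hand contingency fixture", {
  expect_equal(weighted_kappa(c(1, 2, 3), c(1, 2, 2), R = 3)$kappa, 4 / 7,
               tolerance = 1e-12)
  expect_equal(weighted_kappa(c(1, 2, 3), c(1, 2, 2), R = 3)$kappa,
               oracle_kappa(c(1, 2, 3), c(1, 2, 2), 3), tolerance = 1e-12)
  idk <- weighted_kappa(c(1, 3, 5, 2, 4), c(1, 3, 5, 2, 4))
  expect_equal(idk$kappa, 1)
  expect_error(weighted_kappa(c(1, 6), c(1, 2), R = 5), "1..5")
  expect_error(weighted_kappa(1:3, 1:4), "length")
})

test_that("independent identically-distributed ratings give kappa near zero", {
  withr::with_seed(9, {
    r1 <- sample.int(5, 4000, replace = TRUE, prob = c(0.1, 0.2, 0.3, 0.25, 0.15))
    r2 <- sample.int(5, 4000, replace = TRUE, prob = c(0.1, 0.2, 0.3, 0.25, 0.15))
  })
  k <- weighted_kappa(r1, r2)
  expect_lt(abs(k$kappa), 3 * k$se)
  kq <- weighted_kappa(r1, r2, weighting = "quadratic")
  expect_lt(abs(kq$kappa), 3 * kq$se)
})

test_that("every statistic matches brute-force recomputation on random tables", {
  withr::with_seed(1234, {
    for (iter in 1:50) {
      x <- round(rlnorm(10, 3, 1), 1)
      y <- round(192 + 0.3 * x + rnorm(10, sd = 40), 1)
      expect_equal(spearman_with_ci(x, y)$rho, oracle_spearman(x, y),
                   tolerance = 1e-10)
      fit <- ols_with_outliers(x, y)
      o <- oracle_ols(x, y)
      expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
      expect_equal(fit$slope, o$slope, tolerance = 1e-10)
      ba <- bland_altman(x, y)
      expect_equal(ba$crude_loa, oracle_crude_loa(x, y), tolerance = 1e-10)
      reg <- oracle_regression_loa(x, y)
      expect_equal(ba$bias_intercept, reg$c0, tolerance = 1e-10)
      expect_equal(ba$bias_slope, reg$c1, tolerance = 1e-10)
      expect_equal(ba$regression_loa_offset, reg$offset, tolerance = 1e-10)
      icc <- icc_single_2way_mixed(cbind(x, y))
      oi <- oracle_icc(cbind(x, y))
      expect_equal(icc$consistency$value, oi$consistency, tolerance = 1e-10)
      expect_equal(icc$absolute$value, oi$absolute, tolerance = 1e-10)
      r1 <- sample.int(5, 10, replace = TRUE)
      r2 <- pmin(5, pmax(1, r1 + sample(-1:1, 10, replace = TRUE)))
      for (wt in c("linear", "quadratic"))
        expect_equal(weighted_kappa(r1, r2, weighting = wt)$kappa,
                     oracle_kappa(r1, r2, 5, wt), tolerance = 1e-10)
    }
  })
})

test_that("normality checks separate normal from skewed samples", {
  withr::with_seed(500, {
    nrm <- rnorm(500)
    expn <- rexp(500)
  })
  expect_gt(normality_checks(nrm)$shapiro_wilk$p_value, 0.05)
  expect_lt(normality_checks(expn)$shapiro_wilk$p_value, 0.001)
  expect_lt(normality_checks(expn)$kolmogorov_smirnov$p_value, 0.01)
  expect_error(normality_checks(c(1, 2)), "at least 3")
  expect_error(normality_checks(rep(4, 10)), "identical")
})

test_that("the full report is coherent on the identity cohort", {
  co <- data.frame(ct_volume_mm3 = c(5, 80, 200, 450, 900, 1300),
                   mr_volume_mm3 = c(5, 80, 200, 450, 900, 1300))
  rep <- suppressMessages(build_report(co, agreement_config(cac_col = NULL,
                                                            likert_cols = NULL)))
  expect_equal(rep$spearman$rho, 1)
  expect_equal(rep$bland_altman$bias, 0)
  expect_equal(rep$icc$consistency$value, 1)
  expect_equal(rep$icc$absolute$value, 1)
  expect_null(rep$kappa)
})

test_that("the report runs end-to-end on a simulated cohort and logs drops", {
  co <- simulate_cohort(cohort_sim_params(seed = 40L))
  rep <- build_report(co)
  expect_s3_class(rep, "agreement_report")
  expect_true(is.finite(rep$spearman$rho))
  expect_true(is.finite(rep$ols$slope))
  expect_true(is.finite(rep$bland_altman$bias_slope))
  expect_true(is.finite(rep$icc$consistency$value))
  expect_true(is.finite(rep$kappa$kappa))
  expect_true(all(is.finite(unlist(rep$cac$vs_x[c("rho", "p_value")]))))

  co$mr_volume_mm3[3] <- NA
  expect_message(rep2 <- build_report(co), "dropped 1")
  expect_identical(rep2$n, nrow(co) - 1L)

  co2 <- co[, c("ct_volume_mm3", "mr_volume_mm3")]
  expect_message(build_report(co2), "kappa omitted")
})
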