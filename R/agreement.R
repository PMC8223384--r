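#' Spearman rank correlation with Fisher-z confidence interval
#'
#' Spearman's rho computed as the Pearson correlation of mid-ranks (average
#' ranks for ties). The 95% CI uses the Fisher z transform with standard
#' error `1/sqrt(n - 3)`; the two-sided p-value comes from the same z
#' statistic. Asymptotic throughout — adequate for cohort-sized n.
#'
#' @param x,y Paired numeric vectors, length >= 3 (>= 4 for a CI).
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A list: `rho`, `ci` (length 2, NA when n < 4), `p_value`, `n`.
#' @export
spearman_with_ci <- function(x, y, conf_level = 0.95) {
  check_pairs(x, y, min_n = 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: one variable is constant", call. = FALSE)
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (n >= 4L && abs(rho) < 1) {
    z <- atanh(rho)
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(z + c(-q, q) * se)
    p <- 2 * stats::pnorm(-abs(z / se))
  } else if (n >= 4L) {       # |rho| == 1: z is infinite
    ci <- c(rho, rho)
    p <- 0
  } else {
    ci <- c(NA_real_, NA_real_)
    p <- NA_real_
  }
  list(rho = rho, ci = ci, p_value = p, n = n)
}

#' Least-squares fit with standardized-residual outlier screening
#'
#' Ordinary least squares of `y` on `x`. Standardized residuals are raw
#' residuals divided by the residual standard error (n − 2 denominator), not
#' leverage-adjusted — set `type = "studentized"` for the internally
#' studentized variant. Subjects whose absolute standardized residual is at
#' or above the cutoff are flagged, and a sensitivity re-fit excluding them
#' is returned alongside the full fit.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @param cutoff Outlier cutoff on |standardized residual| (default 3).
#' @param type `"standard"` (residual / residual SE) or `"studentized"`
#'   (leverage-adjusted).
#'
#' @return A list: `intercept`, `slope`, `r_squared`, `sigma` (residual SE),
#'   `std_residuals`, `outliers` (indices), `fit_excluding_outliers` (list
#'   with `intercept`, `slope`, `r_squared`, or NULL when nothing was
#'   flagged), `n`.
#' @export
ols_with_outliers <- function(x, y, cutoff = 3, type = c("standard", "studentized")) {
  type <- match.arg(type)
  check_pairs(x, y, min_n = 3L)
  if (stats::sd(x) == 0)
    stop("degenerate fit: x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sfit <- suppressWarnings(summary(fit))   # perfect fits are legitimate here
  sigma <- sfit$sigma
  res <- stats::residuals(fit)
  # a sigma that is pure floating-point residue means an exact fit: the
  # standardized residuals are then 0, not noise ratios
  perfect <- sigma <= 1e-10 * max(abs(y), 1)
  std <- if (perfect) rep(0, length(res))
         else if (type == "standard") res / sigma
         else stats::rstandard(fit)
  out_idx <- unname(which(abs(std) >= cutoff))
  refit <- NULL
  if (length(out_idx) && length(x) - length(out_idx) >= 3L) {
    f2 <- stats::lm(y[-out_idx] ~ x[-out_idx])
    refit <- list(intercept = unname(stats::coef(f2)[1]),
                  slope = unname(stats::coef(f2)[2]),
                  r_squared = suppressWarnings(summary(f2))$r.squared)
  }
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r_squared = sfit$r.squared,
       sigma = sigma, std_residuals = unname(std),
       outliers = out_idx, residual_type = type,
       fit_excluding_outliers = refit, n = length(x))
}

#' Bland-Altman agreement analysis with regression-modelled bias
#'
#' Differences are `y - x` (second method minus first) and means
#' `(x + y)/2`. Reports the crude analysis — mean bias and limits of
#' agreement `bias ± 1.96 × SD(d)` (n − 1 denominator) — and, because
#' proportional bias violates the constant-bias assumption, a
#' regression-based analysis: the bias is modelled by OLS of differences on
#' means, and the 95% limits of agreement are the bias line shifted by
#' `± 1.96 ×` the SD of the regression residuals (n − 2 denominator). 1.96
#' is used verbatim (normal quantile, not t), the convention for 95% limits
#' of agreement.
#'
#' @param x,y Paired numeric vectors (x = reference method, y = comparator),
#'   length >= 3.
#'
#' @return An object of class `bland_altman`: `bias`, `sd_diff`, `crude_loa`
#'   (length 2), `bias_intercept` (c0), `bias_slope` (c1), `slope_p_value`,
#'   `residual_sd`, `regression_loa_offset` (1.96 × residual SD; the LOA
#'   lines are `c0 + c1*m ± offset`), `n`.
#' @export
bland_altman <- function(x, y) {
  check_pairs(x, y, min_n = 3L)
  d <- y - x
  m <- (x + y) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  q <- 1.96
  crude_loa <- bias + c(-q, q) * sd_d

  if (stats::sd(m) == 0) {
    # all means identical: bias line is flat by construction
    c0 <- bias; c1 <- 0; p_slope <- NA_real_
    resid_sd <- if (length(d) > 2) sqrt(sum((d - bias)^2) / (length(d) - 2)) else 0
  } else {
    fit <- stats::lm(d ~ m)
    c0 <- unname(stats::coef(fit)[1])
    c1 <- unname(stats::coef(fit)[2])
    sfit <- suppressWarnings(summary(fit))
    p_slope <- sfit$coefficients[2, 4]
    resid_sd <- sfit$sigma
  }
  structure(list(bias = bias, sd_diff = sd_d, crude_loa = crude_loa,
                 bias_intercept = c0, bias_slope = c1,
                 slope_p_value = p_slope, residual_sd = resid_sd,
                 regression_loa_offset = q * resid_sd, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d\n  mean bias %.3f, crude 95%% LOA [%.3f, %.3f]\n  bias model: %.3f %+.3f * mean (slope p = %.3g), 95%% LOA offset +/- %.3f\n",
              x$n, x$bias, x$crude_loa[1], x$crude_loa[2],
              x$bias_intercept, x$bias_slope, x$slope_p_value,
              x$regression_loa_offset))
  invisible(x)
}

#' Two-way mixed single-measure intraclass correlation
#'
#' ICC from the two-way (subjects x raters/methods) ANOVA mean squares,
#' single-rating, mixed model, in both conventional variants:
#' consistency `(MSR - MSE) / (MSR + (k-1) MSE)` and absolute agreement
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`. Confidence
#' intervals follow the McGraw-Wong F-based formulas (Satterthwaite degrees
#' of freedom for the absolute variant). The variant and model tags are
#' carried in the output, since ICC labelling is notoriously ambiguous.
#'
#' @param ratings An `n x k` numeric matrix (or data frame): n subjects in
#'   rows, k raters or methods in columns. Must be complete — missing cells
#'   are an error, not imputed.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A list of two `icc_estimate`s, `consistency` and `absolute`, each
#'   with `value`, `ci`, `variant`, `model`, plus shared `mean_squares`
#'   (MSR, MSC, MSE), `n`, `k`, and the F-test `p_value` (H0: ICC = 0).
#' @export
icc_single_2way_mixed <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings))
    stop("ratings table is incomplete; missing cells are not imputed",
         call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L || k < 2L)
    stop("need at least 3 subjects and 2 raters/methods", call. = FALSE)

  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  alpha <- 1 - conf_level
  icc_c <- (msr - mse) / (msr + (k - 1) * mse)
  icc_a <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # consistency CI: exact F interval
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  if (mse > 0) {
    f_obs <- msr / mse
    fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
    ci_c <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    p <- stats::pf(f_obs, df1, df2, lower.tail = FALSE)
  } else {
    ci_c <- c(icc_c, icc_c)
    p <- 0
  }

  # absolute-agreement CI: Satterthwaite df
  if (mse > 0 && icc_a < 1) {
    aa <- (k * icc_a) / (n * (1 - icc_a))
    bb <- 1 + (k * icc_a * (n - 1)) / (n * (1 - icc_a))
    v <- (aa * msc + bb * mse)^2 /
      ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
    fl_a <- stats::qf(1 - alpha / 2, n - 1, v)
    fu_a <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl_a * mse) /
      (fl_a * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu_a * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu_a * msr)
    ci_a <- c(lower, upper)
  } else {
    ci_a <- c(icc_a, icc_a)
  }

  list(
    consistency = structure(list(value = icc_c, ci = ci_c,
                                 variant = "consistency",
                                 model = "single-rating, 2-way mixed"),
                            class = "icc_estimate"),
    absolute = structure(list(value = icc_a, ci = ci_a,
                              variant = "absolute agreement",
                              model = "single-rating, 2-way mixed"),
                         class = "icc_estimate"),
    mean_squares = c(MSR = msr, MSC = msc, MSE = mse),
    p_value = p, n = n, k = k
  )
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC (%s, %s): %.3f [%.3f, %.3f]\n",
              x$variant, x$model, x$value, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Weighted Cohen's kappa for paired ordinal ratings
#'
#' Chance-corrected agreement between two raters on an ordinal scale
#' `1..R`, with distance-dependent disagreement weights
#' `w_ij = |i - j| / (R - 1)` (linear, the default) or its square
#' (quadratic). Kappa is `1 - sum(w * p_obs) / sum(w * p_exp)` with expected
#' proportions from the marginal products. The CI uses the standard
#' large-sample (Fleiss-Cohen-Everitt) standard error.
#'
#' @param r1,r2 Integer rating vectors of equal length, values in `1..R`.
#' @param R Number of scale points (default 5, a Likert scale).
#' @param weighting `"linear"` or `"quadratic"`.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A list: `kappa`, `se`, `ci`, `weighting`, `n`.
#' @export
weighted_kappa <- function(r1, r2, R = 5L, weighting = c("linear", "quadratic"),
                           conf_level = 0.95) {
  weighting <- match.arg(weighting)
  if (length(r1) != length(r2))
    stop("rating vectors differ in length", call. = FALSE)
  r1 <- as.integer(r1); r2 <- as.integer(r2)
  if (anyNA(r1) || anyNA(r2) || any(r1 < 1L | r1 > R) || any(r2 < 1L | r2 > R))
    stop("ratings must be integers in 1..", R, call. = FALSE)
  n <- length(r1)
  if (n < 2L) stop("need at least 2 paired ratings", call. = FALSE)

  p <- table(factor(r1, levels = 1:R), factor(r2, levels = 1:R)) / n
  p <- as.matrix(p)
  pr <- rowSums(p); pc <- colSums(p)
  w <- abs(outer(1:R, 1:R, `-`)) / (R - 1)
  if (weighting == "quadratic") w <- w^2
  u <- 1 - w                                  # agreement weights
  po <- sum(u * p)
  pe <- sum(u * outer(pr, pc))
  if (pe >= 1) {  # both raters constant on the same category
    return(list(kappa = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                weighting = weighting, n = n))
  }
  kap <- (po - pe) / (1 - pe)

  # large-sample SE (Fleiss, Cohen & Everitt)
  ubar_i <- as.vector(u %*% pc)              # sum_j p.j * u_ij
  ubar_j <- as.vector(pr %*% u)              # sum_i pi. * u_ij
  term <- (u - outer(ubar_i, ubar_j, `+`) * (1 - kap))^2
  var_hat <- (sum(p * term) - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(var_hat, 0))
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kap, se = se, ci = kap + c(-q, q) * se,
       weighting = weighting, n = n)
}

#' Normality checks
#'
#' Shapiro-Wilk and Kolmogorov-Smirnov (against a normal with moment-matched
#' parameters) tests. Advisory: in the agreement report they motivate
#' displaying Spearman rather than Pearson correlation; no decision is
#' automated on them.
#'
#' @param values Numeric vector, length >= 3, non-constant.
#'
#' @return A list with `shapiro_wilk` and `kolmogorov_smirnov`, each holding
#'   `statistic` and `p_value`.
#' @export
normality_checks <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L)
    stop("need at least 3 values for normality tests", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate input: all values identical", call. = FALSE)
  sw <- stats::shapiro.test(if (length(values) > 5000) values[1:5000] else values)
  ks <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  list(shapiro_wilk = list(statistic = unname(sw$statistic),
                           p_value = sw$p.value),
       kolmogorov_smirnov = list(statistic = unname(ks$statistic),
                                 p_value = ks$p.value))
}

# shared pair validation
check_pairs <- function(x, y, min_n = 3L) {
  if (length(x) != length(y))
    stop("x and y differ in length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values: exclude incomplete pairs upstream", call. = FALSE)
  if (length(x) < min_n)
    stop("need at least ", min_n, " pairs", call. = FALSE)
  invisible(TRUE)
}
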