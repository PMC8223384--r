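#' Options for the agreement report
#'
#' @param x_col,y_col Cohort columns holding the reference (CT) and
#'   comparator (MR) volumes.
#' @param cac_col Optional column with the coronary Agatston score; `NULL`
#'   skips the CAC correlations.
#' @param likert_cols Optional pair of columns with two observers' ordinal
#'   quality ratings; `NULL` skips kappa.
#' @param outlier_cutoff Cutoff on |standardized residual| (default 3).
#' @param kappa_weighting `"linear"` (default) or `"quadratic"`.
#' @param residual_type Passed to [ols_with_outliers()].
#'
#' @return An `agreement_config` list.
#' @export
agreement_config <- function(x_col = "ct_volume_mm3", y_col = "mr_volume_mm3",
                             cac_col = "cac_agatston",
                             likert_cols = c("likert_obs1", "likert_obs2"),
                             outlier_cutoff = 3,
                             kappa_weighting = "linear",
                             residual_type = "standard") {
  structure(list(x_col = x_col, y_col = y_col, cac_col = cac_col,
                 likert_cols = likert_cols, outlier_cutoff = outlier_cutoff,
                 kappa_weighting = kappa_weighting,
                 residual_type = residual_type),
            class = "agreement_config")
}

#' Full method-agreement report for a measurement cohort
#'
#' Runs the complete comparison of the two volume measurements: normality
#' checks, Spearman correlation (volumes and, when available, each
#' modality's volume against the coronary Agatston score), OLS with
#' standardized-residual outlier screening plus the sensitivity re-fit,
#' crude and regression-based Bland-Altman limits of agreement, two-way
#' mixed single-measure ICC in both variants, and — when two observers'
#' ordinal ratings are present — weighted Cohen's kappa. Subjects with any
#' missing required value are dropped listwise with a logged count.
#'
#' @param cohort Data frame of per-subject measurements (see
#'   [simulate_cohort()] for the expected columns).
#' @param config An [agreement_config()].
#'
#' @return An object of class `agreement_report`.
#' @export
build_report <- function(cohort, config = agreement_config()) {
  stopifnot(is.data.frame(cohort), inherits(config, "agreement_config"))
  for (col in c(config$x_col, config$y_col))
    if (!col %in% names(cohort))
      stop("cohort is missing required column '", col, "'", call. = FALSE)

  required <- c(config$x_col, config$y_col)
  if (!is.null(config$cac_col) && config$cac_col %in% names(cohort))
    required <- c(required, config$cac_col)
  complete <- stats::complete.cases(cohort[required])
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message("dropped ", n_dropped, " subject(s) with missing values")
  cohort <- cohort[complete, , drop = FALSE]

  x <- cohort[[config$x_col]]
  y <- cohort[[config$y_col]]

  # advisory only: a degenerate vector (e.g. identical methods giving
  # constant differences) is reported as such, not fatal
  safe_normality <- function(v) {
    tryCatch(normality_checks(v),
             error = function(e) list(degenerate = conditionMessage(e)))
  }
  normality <- list(x = safe_normality(x), y = safe_normality(y),
                    differences = safe_normality(y - x))
  spearman <- spearman_with_ci(x, y)
  ols <- ols_with_outliers(x, y, cutoff = config$outlier_cutoff,
                           type = config$residual_type)
  ba <- bland_altman(x, y)
  icc <- icc_single_2way_mixed(cbind(x, y))

  cac <- NULL
  if (!is.null(config$cac_col) && config$cac_col %in% names(cohort)) {
    cv <- cohort[[config$cac_col]]
    cac <- list(vs_x = spearman_with_ci(x, cv),
                vs_y = spearman_with_ci(y, cv))
  }

  kappa <- NULL
  lcols <- config$likert_cols
  if (!is.null(lcols) && all(lcols %in% names(cohort))) {
    lik <- cohort[lcols]
    ok <- stats::complete.cases(lik)
    if (sum(ok) >= 2L)
      kappa <- weighted_kappa(lik[[1]][ok], lik[[2]][ok],
                              weighting = config$kappa_weighting)
  } else {
    message("no observer rating columns found; kappa omitted")
  }

  structure(list(n = length(x), n_dropped = n_dropped,
                 normality = normality, spearman = spearman, ols = ols,
                 bland_altman = ba, icc = icc, cac = cac, kappa = kappa,
                 config = config),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d (%d dropped)\n", x$n, x$n_dropped))
  cat(sprintf("  Spearman rho = %.3f [%.3f, %.3f], p = %.3g\n",
              x$spearman$rho, x$spearman$ci[1], x$spearman$ci[2],
              x$spearman$p_value))
  cat(sprintf("  OLS: y = %.2f %+.3f x (R^2 = %.3f), %d outlier(s)\n",
              x$ols$intercept, x$ols$slope, x$ols$r_squared,
              length(x$ols$outliers)))
  cat(sprintf("  Bias model: %.2f %+.3f * mean, LOA offset +/- %.2f\n",
              x$bland_altman$bias_intercept, x$bland_altman$bias_slope,
              x$bland_altman$regression_loa_offset))
  print(x$icc$consistency); print(x$icc$absolute)
  if (!is.null(x$kappa))
    cat(sprintf("  Weighted kappa (%s) = %.3f [%.3f, %.3f]\n",
                x$kappa$weighting, x$kappa$kappa, x$kappa$ci[1], x$kappa$ci[2]))
  invisible(x)
}

#' Serialize an agreement report to JSON
#'
#' Writes the full report, including the configuration that produced it, as
#' deterministic JSON (fixed 10-digit precision, so identical analyses yield
#' byte-identical files).
#'
#' @param report An `agreement_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- report_to_list(report)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null")
  invisible(path)
}

report_to_list <- function(report) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  out <- strip(unclass(report))
  out$schema_version <- "1.0"
  out
}
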