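# Independent brute-force recomputations used to validate the statistics.
# Everything here is naive loops over ranks, contingency cells and ANOVA
# sums of squares -- deliberately a different route from the implementation.

oracle_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- 0; equal <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) less <- less + 1
      if (x[j] == x[i]) equal <- equal + 1
    }
    r[i] <- less + (equal + 1) / 2
  }
  r
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

oracle_spearman <- function(x, y)
  oracle_pearson(oracle_midranks(x), oracle_midranks(y))

oracle_ols <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
  }
  slope <- sxy / sxx
  intercept <- my - slope * mx
  sse <- 0
  for (i in seq_len(n)) sse <- sse + (y[i] - intercept - slope * x[i])^2
  list(intercept = intercept, slope = slope,
       resid_sd = sqrt(sse / (n - 2)))
}

oracle_icc <- function(mat) {
  mat <- unname(as.matrix(mat))
  n <- nrow(mat); k <- ncol(mat)
  grand <- sum(mat) / (n * k)
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in seq_len(n)) {
    rm_i <- sum(mat[i, ]) / k
    ssr <- ssr + k * (rm_i - grand)^2
  }
  for (j in seq_len(k)) {
    cm_j <- sum(mat[, j]) / n
    ssc <- ssc + n * (cm_j - grand)^2
  }
  for (i in seq_len(n)) for (j in seq_len(k))
    sst <- sst + (mat[i, j] - grand)^2
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  list(consistency = (msr - mse) / (msr + (k - 1) * mse),
       absolute = (msr - mse) /
         (msr + (k - 1) * mse + (k / n) * (msc - mse)),
       msr = msr, msc = msc, mse = mse)
}

oracle_kappa <- function(r1, r2, R, weighting = "linear") {
  n <- length(r1)
  obs <- matrix(0, R, R)
  for (s in seq_len(n)) obs[r1[s], r2[s]] <- obs[r1[s], r2[s]] + 1 / n
  po_w <- 0; pe_w <- 0
  for (i in seq_len(R)) for (j in seq_len(R)) {
    w <- abs(i - j) / (R - 1)
    if (weighting == "quadratic") w <- w^2
    pi_ <- sum(obs[i, ]); p_j <- sum(obs[, j])
    po_w <- po_w + w * obs[i, j]
    pe_w <- pe_w + w * pi_ * p_j
  }
  1 - po_w / pe_w
}

oracle_crude_loa <- function(x, y) {
  d <- y - x
  n <- length(d)
  bias <- sum(d) / n
  ssd <- 0
  for (i in seq_len(n)) ssd <- ssd + (d[i] - bias)^2
  sdd <- sqrt(ssd / (n - 1))
  c(bias - 1.96 * sdd, bias + 1.96 * sdd)
}

oracle_regression_loa <- function(x, y) {
  d <- y - x
  m <- (x + y) / 2
  fit <- oracle_ols(m, d)
  list(c0 = fit$intercept, c1 = fit$slope, resid_sd = fit$resid_sd,
       offset = 1.96 * fit$resid_sd)
}

# brute-force circular median filter with edge replication
oracle_median_slice <- function(slice, radius_mm, dx, dy) {
  nr <- nrow(slice); nc <- ncol(slice)
  out <- slice
  ri <- floor(radius_mm / dx); rj <- floor(radius_mm / dy)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -ri:ri) for (dj in -rj:rj) {
      if ((di * dx)^2 + (dj * dy)^2 > radius_mm^2 + 1e-12) next
      si <- min(max(i + di, 1), nr)
      sj <- min(max(j + dj, 1), nc)
      vals <- c(vals, slice[si, sj])
    }
    out[i, j] <- median(vals)
  }
  out
}
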