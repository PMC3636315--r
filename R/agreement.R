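# Between-series agreement: mean difference, SD of differences, Pearson
# correlation with Fisher intervals, and Deming errors-in-variables
# regression with jackknife intervals, stratified as in the study tables.

#' Paired between-series sample
#'
#' @param x thresholds from the reference series (dB).
#' @param y thresholds from the compared series (dB).
#' @param label stratum tag (a frequency, `"total"`, `"mean"`, or a
#'   threshold-group tag).
#' @return object of class `paired_sample`.
#' @export
paired_sample <- function(x, y, label = "total") {
  if (length(x) != length(y))
    data_error("paired sample requires equal-length x and y")
  keep <- is.finite(x) & is.finite(y)
  structure(list(x = x[keep], y = y[keep], label = label),
            class = "paired_sample")
}

#' Mean and SD of paired differences
#'
#' @param s a [paired_sample()].
#' @return list with `m` (mean of y - x) and `sigma` (sample SD, n-1
#'   denominator).
#' @export
mean_sd_difference <- function(s) {
  d <- s$y - s$x
  if (length(d) < 2) data_error("need at least 2 pairs for a difference SD")
  list(m = mean(d), sigma = stats::sd(d))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param s a [paired_sample()].
#' @param alpha two-sided significance level (default 0.05).
#' @return list with `r`, `lo`, `hi`.
#' @export
pearson_with_ci <- function(s, alpha = 0.05) {
  n <- length(s$x)
  if (n < 4) data_error("need at least 4 pairs for a correlation CI")
  if (stats::sd(s$x) == 0 || stats::sd(s$y) == 0)
    data_error("correlation undefined for a constant series")
  r <- stats::cor(s$x, s$y)
  ci <- fisher_ci(r, n, alpha)
  list(r = r, lo = ci[1], hi = ci[2])
}

#' Fisher-z interval for a correlation coefficient
#'
#' @param r correlation estimate.
#' @param n sample size (> 3).
#' @param alpha two-sided significance level.
#' @return numeric `c(lo, hi)`.
#' @export
fisher_ci <- function(r, n, alpha = 0.05) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - alpha / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Deming errors-in-variables regression
#'
#' Closed-form moment estimator of `y = a x + b` when both variables carry
#' measurement error, with `delta` the ratio of the y-error variance to the
#' x-error variance:
#' `a = (s_yy - delta s_xx + sqrt((s_yy - delta s_xx)^2 + 4 delta s_xy^2)) /
#' (2 s_xy)`, `b = mean(y) - a mean(x)`. At `delta = 1` this is orthogonal
#' regression.
#'
#' @param s a [paired_sample()].
#' @param delta error-variance ratio (> 0), default 1.
#' @return list with `slope`, `intercept`, `delta`.
#' @export
deming_fit <- function(s, delta = 1) {
  if (delta <= 0) config_error("delta must be positive")
  n <- length(s$x)
  if (n < 3) data_error("need at least 3 pairs for a Deming fit")
  sxx <- stats::var(s$x); syy <- stats::var(s$y)
  sxy <- stats::cov(s$x, s$y)
  if (sxy == 0) {
    if (syy == 0 && sxx == 0)
      data_error("degenerate Deming fit: no variance in either variable")
    data_error("degenerate Deming fit: zero covariance")
  }
  slope <- (syy - delta * sxx + sqrt((syy - delta * sxx)^2 +
                                     4 * delta * sxy^2)) / (2 * sxy)
  list(slope = slope, intercept = mean(s$y) - slope * mean(s$x),
       delta = delta)
}

#' Jackknife confidence intervals for the Deming fit
#'
#' Leave-one-out jackknife standard errors with normal-quantile intervals
#' around the full-sample estimates.
#'
#' @param s a [paired_sample()] with at least 10 pairs.
#' @param delta error-variance ratio.
#' @param alpha two-sided significance level.
#' @return list with `slope`, `slope_lo`, `slope_hi`, `intercept`,
#'   `intercept_lo`, `intercept_hi`.
#' @export
deming_ci <- function(s, delta = 1, alpha = 0.05) {
  n <- length(s$x)
  if (n < 10) data_error("need at least 10 pairs for jackknife intervals")
  full <- deming_fit(s, delta)
  # leave-one-out fits via O(1) moment updates (vectorized over i)
  x <- s$x; y <- s$y
  m <- n - 1
  mx <- (sum(x) - x) / m
  my <- (sum(y) - y) / m
  sxx <- (sum(x^2) - x^2 - m * mx^2) / (m - 1)
  syy <- (sum(y^2) - y^2 - m * my^2) / (m - 1)
  sxy <- (sum(x * y) - x * y - m * mx * my) / (m - 1)
  slope_i <- (syy - delta * sxx +
                sqrt(pmax(0, (syy - delta * sxx)^2 + 4 * delta * sxy^2))) /
    (2 * sxy)
  int_i <- my - slope_i * mx
  loo <- rbind(unname(slope_i), unname(int_i))
  se <- unname(sqrt((n - 1) / n * rowSums((loo - rowMeans(loo))^2)))
  q <- stats::qnorm(1 - alpha / 2)
  list(slope = full$slope,
       slope_lo = full$slope - q * se[1], slope_hi = full$slope + q * se[1],
       intercept = full$intercept,
       intercept_lo = full$intercept - q * se[2],
       intercept_hi = full$intercept + q * se[2])
}

#' Build the stratified paired samples for a series pairing
#'
#' Pairs the thresholds of two series by subject, ear and frequency,
#' dropping pairs where either series has no response, and emits one
#' [paired_sample()] per frequency, one pooled `"total"` sample, one
#' per-ear `"mean"` sample (mean across the frequencies with complete pairs
#' for that ear), and two hearing-threshold groups (`"t<40"`, `"t>=40"`)
#' where a pair is assigned by the mean of its two series values.
#'
#' @param measurements measurement data frame (columns `subject_id`, `ear`,
#'   `series`, `frequency_hz`, `level_db`, `no_response`).
#' @param pairing length-2 vector of series ids, e.g. `c(1, 2)`.
#' @param grid frequency grid.
#' @param group_cutoff threshold-group boundary in dB (default 40).
#' @param mean_requires_complete if `TRUE`, the per-ear mean uses only ears
#'   with complete pairs at every frequency; default `FALSE` averages the
#'   frequencies available for each ear.
#' @return named list of `paired_sample` objects.
#' @export
stratify <- function(measurements, pairing = c(1, 2), grid = default_grid(),
                     group_cutoff = 40, mean_requires_complete = FALSE) {
  a <- measurements[measurements$series == pairing[1], ]
  b <- measurements[measurements$series == pairing[2], ]
  if (nrow(a) == 0 || nrow(b) == 0)
    data_error("both series of the pairing must be present")
  key <- function(d) paste(d$subject_id, d$ear, d$frequency_hz, sep = "|")
  m <- merge(
    data.frame(key = key(a), frequency_hz = a$frequency_hz,
               subject_id = a$subject_id, ear = a$ear,
               x = a$level_db, x_nr = a$no_response),
    data.frame(key = key(b), y = b$level_db, y_nr = b$no_response),
    by = "key")
  m <- m[!m$x_nr & !m$y_nr & is.finite(m$x) & is.finite(m$y), ]
  if (nrow(m) == 0) data_error("no complete pairs in the pairing")

  out <- list()
  for (f in grid) {
    sub <- m[m$frequency_hz == f, ]
    out[[as.character(f)]] <- paired_sample(sub$x, sub$y, as.character(f))
  }
  out[["total"]] <- paired_sample(m$x, m$y, "total")

  ear_key <- paste(m$subject_id, m$ear, sep = "|")
  if (mean_requires_complete) {
    complete <- names(which(table(ear_key) == length(grid)))
    keep <- ear_key %in% complete
    mx <- tapply(m$x[keep], ear_key[keep], mean)
    my <- tapply(m$y[keep], ear_key[keep], mean)
  } else {
    mx <- tapply(m$x, ear_key, mean)
    my <- tapply(m$y, ear_key, mean)
  }
  out[["mean"]] <- paired_sample(as.numeric(mx), as.numeric(my), "mean")

  pair_mean <- (m$x + m$y) / 2
  lo <- pair_mean < group_cutoff
  out[[sprintf("t<%g", group_cutoff)]] <-
    paired_sample(m$x[lo], m$y[lo], sprintf("t<%g", group_cutoff))
  out[[sprintf("t>=%g", group_cutoff)]] <-
    paired_sample(m$x[!lo], m$y[!lo], sprintf("t>=%g", group_cutoff))
  out
}

#' Agreement summary table for a series pairing
#'
#' One row per stratum with the pair count, mean difference, SD of
#' differences, Pearson correlation with Fisher interval, and Deming slope
#' and intercept with jackknife intervals. Strata too small or too
#' degenerate for a statistic carry `NA` in its columns.
#'
#' @param samples named list from [stratify()].
#' @param delta Deming error-variance ratio.
#' @param alpha two-sided significance level.
#' @return data frame with columns `stratum`, `n`, `m`, `sigma`, `r`,
#'   `r_lo`, `r_hi`, `a`, `a_lo`, `a_hi`, `b`, `b_lo`, `b_hi`.
#' @export
agreement_table <- function(samples, delta = 1, alpha = 0.05) {
  rows <- lapply(samples, function(s) {
    n <- length(s$x)
    row <- data.frame(stratum = s$label, n = n, m = NA_real_,
                      sigma = NA_real_, r = NA_real_, r_lo = NA_real_,
                      r_hi = NA_real_, a = NA_real_, a_lo = NA_real_,
                      a_hi = NA_real_, b = NA_real_, b_lo = NA_real_,
                      b_hi = NA_real_)
    if (n >= 2) {
      ms <- mean_sd_difference(s)
      row$m <- ms$m; row$sigma <- ms$sigma
    }
    ok_r <- n >= 4 && stats::sd(s$x) > 0 && stats::sd(s$y) > 0
    if (ok_r) {
      pc <- pearson_with_ci(s, alpha)
      row$r <- pc$r; row$r_lo <- pc$lo; row$r_hi <- pc$hi
    }
    if (n >= 10 && ok_r && stats::cov(s$x, s$y) != 0) {
      dc <- deming_ci(s, delta, alpha)
      row$a <- dc$slope; row$a_lo <- dc$slope_lo; row$a_hi <- dc$slope_hi
      row$b <- dc$intercept; row$b_lo <- dc$intercept_lo
      row$b_hi <- dc$intercept_hi
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
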