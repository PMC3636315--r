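# Variance decomposition of the web-test measurement error.
#
# All components are treated as independent and additive in variance, so a
# component hidden inside a between-series difference SD is isolated by
# subtracting the variances of the known components and taking the square
# root. Estimates whose radicand goes negative (sampling noise pushing a
# small component below zero) are clamped to 0 and flagged.

#' Variance subtraction of independent error components
#'
#' `sqrt(max(0, sigma_total^2 - sum(components^2)))`. The clamp to zero is
#' the package-wide convention for negative radicands; the flag records
#' when it fired.
#'
#' @param sigma_total SD of the composite, dB.
#' @param components SDs of the components to remove, dB.
#' @return list with `sd` and `clamped`.
#' @export
#' @examples
#' var_subtract(5, c(3, 4))     # 0, not clamped
#' var_subtract(7.88, 4.25)     # about 6.64
var_subtract <- function(sigma_total, components = numeric(0)) {
  if (any(!is.finite(c(sigma_total, components))) ||
      sigma_total < 0 || any(components < 0))
    domain_error("SDs must be finite and >= 0")
  rad <- sigma_total^2 - sum(components^2)
  list(sd = sqrt(max(0, rad)), clamped = rad < 0)
}

#' Single-measurement SD from a test-retest SD
#'
#' A test-retest difference is the difference of two independent
#' measurements, so one measurement's SD is the test-retest SD divided by
#' sqrt(2).
#'
#' @param sigma_testretest SD of the difference of two repeated
#'   measurements, dB.
#' @return single-measurement SD, dB.
#' @export
single_measurement_sd <- function(sigma_testretest) {
  if (!is.finite(sigma_testretest) || sigma_testretest < 0)
    domain_error("test-retest SD must be finite and >= 0")
  sigma_testretest / sqrt(2)
}

#' Adopt a clinical test-retest SD from literature data
#'
#' Averages a table of published test-retest SDs: first the mean per
#' frequency across studies/series (ignoring missing cells), then the mean
#' across frequencies, rounded to the nearest integer dB as the adopted
#' working value.
#'
#' @param table3 data frame of per-frequency SDs; frequency columns are
#'   selected by `freq_cols`.
#' @param freq_cols names of the frequency columns.
#' @return list with `adopted` (integer dB), `per_frequency` (named means)
#'   and `grand_mean` (unrounded).
#' @export
adopt_testretest_sd <- function(table3,
                                freq_cols = c("f250", "f500", "f1000",
                                              "f2000", "f4000", "f8000")) {
  if (is.null(table3) || nrow(table3) == 0)
    data_error("empty test-retest table")
  if (!all(freq_cols %in% names(table3)))
    data_error("test-retest table must cover all frequency columns")
  per_freq <- vapply(freq_cols, function(cn)
    mean(table3[[cn]], na.rm = TRUE), numeric(1))
  grand <- mean(per_freq)
  list(adopted = round_half_up(grand, 0), per_frequency = per_freq,
       grand_mean = grand)
}

#' Web-series procedure error from a between-series SD
#'
#' Removes the clinical measurement error from the SD of the difference
#' between the clinical series and a web series. Applied to the supervised
#' series this yields the self-adjustment procedure SD; applied to the home
#' series it yields that series' total web-test error SD.
#'
#' @param sigma_between SD of the between-series differences, dB.
#' @param sigma_clin single clinical measurement SD, dB.
#' @return list with `sd` and `clamped`.
#' @export
series_error_sd <- function(sigma_between, sigma_clin) {
  var_subtract(sigma_between, sigma_clin)
}

#' Calibration error from the two web series at 1 kHz
#'
#' At the calibration frequency the nonlinearity error is zero by
#' construction, so the home-series excess over the supervised series there
#' is the calibration error alone.
#'
#' @param sigma3_1k between-series SD (clinical vs home) at 1 kHz, dB.
#' @param sigma2_1k between-series SD (clinical vs supervised) at 1 kHz, dB.
#' @return list with `sd` and `clamped`.
#' @export
calibration_sd <- function(sigma3_1k, sigma2_1k) {
  var_subtract(sigma3_1k, sigma2_1k)
}

#' Per-frequency nonlinearity error SDs
#'
#' For each frequency other than 1 kHz, removes the supervised-series SD
#' and the calibration error from the home-series SD; at 1 kHz the value is
#' 0 by construction. The mean is taken over the non-calibration
#' frequencies, with clamped zeros included.
#'
#' @param diff_table a difference-SD table, see [difference_sd_table()].
#' @param sigma_cal calibration error SD, dB (carry it unrounded).
#' @param grid frequency grid.
#' @param cal_frequency calibration frequency, Hz.
#' @return list with `per_frequency` (named SDs), `clamped` (named
#'   logicals), `mean` (over non-calibration frequencies).
#' @export
nonlinearity_sds <- function(diff_table, sigma_cal, grid = default_grid(),
                             cal_frequency = 1000) {
  sds <- stats::setNames(numeric(length(grid)), as.character(grid))
  clamped <- stats::setNames(logical(length(grid)), as.character(grid))
  for (f in grid) {
    key <- as.character(f)
    if (f == cal_frequency) next
    s2 <- diff_lookup(diff_table, "1v2", key)
    s3 <- diff_lookup(diff_table, "1v3", key)
    v <- var_subtract(s3, c(s2, sigma_cal))
    sds[[key]] <- v$sd
    clamped[[key]] <- v$clamped
  }
  others <- as.character(grid[grid != cal_frequency])
  list(per_frequency = sds, clamped = clamped, mean = mean(sds[others]))
}

#' Reference-population SD at the calibration frequency
#'
#' Removes the ascending-method measurement error from the literature SD of
#' ascending-method thresholds among young normal-hearing subjects, leaving
#' the true population spread of reference persons' thresholds.
#'
#' @param sigma_pop_asc literature SD of ascending-method thresholds in the
#'   reference population, dB (default 5.6).
#' @param sigma_clin single clinical measurement SD, dB.
#' @return list with `sd` and `clamped`.
#' @export
population_sd <- function(sigma_pop_asc, sigma_clin) {
  var_subtract(sigma_pop_asc, sigma_clin)
}

#' Calibration-task SD
#'
#' Removes the reference-population spread from the calibration error,
#' leaving the error of the paired-tone threshold task itself.
#'
#' @param sigma_cal calibration error SD, dB.
#' @param sigma_pop reference-population SD, dB.
#' @return list with `sd` and `clamped`.
#' @export
calibration_task_sd <- function(sigma_cal, sigma_pop) {
  var_subtract(sigma_cal, sigma_pop)
}

#' Difference-SD table constructor
#'
#' Holds the per-stratum SDs of between-series differences: one entry per
#' (pairing, stratum) with pairings `"1v2"` (clinical vs supervised) and
#' `"1v3"` (clinical vs home) and strata the frequencies plus `"total"`.
#'
#' @param pairing character vector (`"1v2"`/`"1v3"`).
#' @param stratum character vector (frequency in Hz or `"total"`).
#' @param sigma nonnegative SDs, dB.
#' @return data frame of class `difference_sd_table`.
#' @export
difference_sd_table <- function(pairing, stratum, sigma) {
  if (any(sigma < 0)) domain_error("difference SDs must be >= 0")
  structure(data.frame(pairing = as.character(pairing),
                       stratum = as.character(stratum), sigma = sigma),
            class = c("difference_sd_table", "data.frame"))
}

diff_lookup <- function(tbl, pairing, stratum) {
  hit <- tbl$sigma[tbl$pairing == pairing & tbl$stratum == stratum]
  if (length(hit) != 1)
    data_error("difference-SD table is missing (%s, %s)", pairing, stratum)
  hit
}

#' Build a difference-SD table from agreement summaries
#'
#' @param agreement_1v2,agreement_1v3 data frames from [agreement_table()]
#'   for the pairings (1,2) and (1,3).
#' @param grid frequency grid.
#' @return a [difference_sd_table()].
#' @export
diff_table_from_agreement <- function(agreement_1v2, agreement_1v3,
                                      grid = default_grid()) {
  strata <- c(as.character(grid), "total")
  pick <- function(tbl, s) {
    v <- tbl$sigma[tbl$stratum == s]
    if (length(v) != 1 || is.na(v))
      data_error("agreement table is missing stratum '%s'", s)
    v
  }
  difference_sd_table(
    pairing = rep(c("1v2", "1v3"), each = length(strata)),
    stratum = rep(strata, 2),
    sigma = c(vapply(strata, pick, numeric(1), tbl = agreement_1v2),
              vapply(strata, pick, numeric(1), tbl = agreement_1v3)))
}

#' Full measurement-error decomposition
#'
#' Chains the variance algebra into a complete error budget:
#' test-retest SD (adopted from the literature table or supplied directly)
#' -> single clinical SD -> procedure SD (from the supervised pairing's
#' total) and home-series SD (from the home pairing's total) -> calibration
#' SD (1 kHz comparison) -> per-frequency nonlinearity SDs and their mean
#' -> population SD and calibration-task SD. Gain and background-noise SDs
#' are set to 0 in the default chain (their observed effect on the series
#' SDs is negligible); both can be overridden for sensitivity analysis.
#'
#' @param diff_table a [difference_sd_table()] covering both pairings at
#'   every grid frequency plus `"total"`.
#' @param testretest_table literature test-retest table for
#'   [adopt_testretest_sd()]; ignored when `sigma_testretest` is given.
#' @param sigma_testretest direct test-retest SD override, dB.
#' @param sigma_pop_asc literature SD of ascending thresholds in the
#'   reference population, dB.
#' @param sigma_gain,sigma_noise overrides for the gain and noise SDs, dB.
#' @param grid frequency grid.
#' @return object of class `error_budget`: a list with the decomposed SDs
#'   (`sigma_clin`, `sigma_testretest`, `sigma_proc`, `sigma_series3`,
#'   `sigma_cal`, `sigma_nonlin` (named), `sigma_nonlin_mean`,
#'   `sigma_gain`, `sigma_noise`, `sigma_pop`, `sigma_proc_cal`,
#'   `sigma_pop_asc`) and a named logical `clamped`.
#' @export
decompose <- function(diff_table, testretest_table = NULL,
                      sigma_testretest = NULL, sigma_pop_asc = 5.6,
                      sigma_gain = 0, sigma_noise = 0,
                      grid = default_grid()) {
  if (is.null(sigma_testretest)) {
    if (is.null(testretest_table))
      data_error("either a test-retest table or sigma_testretest is required")
    sigma_testretest <- adopt_testretest_sd(testretest_table)$adopted
  }
  sigma_clin <- single_measurement_sd(sigma_testretest)

  proc <- series_error_sd(diff_lookup(diff_table, "1v2", "total"), sigma_clin)
  s3 <- series_error_sd(diff_lookup(diff_table, "1v3", "total"), sigma_clin)
  cal <- calibration_sd(diff_lookup(diff_table, "1v3", "1000"),
                        diff_lookup(diff_table, "1v2", "1000"))
  nl <- nonlinearity_sds(diff_table, cal$sd, grid)
  pop <- population_sd(sigma_pop_asc, sigma_clin)
  pc <- calibration_task_sd(cal$sd, pop$sd)

  clamped <- c(sigma_proc = proc$clamped, sigma_series3 = s3$clamped,
               sigma_cal = cal$clamped,
               stats::setNames(nl$clamped,
                               paste0("sigma_nonlin_", names(nl$clamped))),
               sigma_pop = pop$clamped, sigma_proc_cal = pc$clamped)

  structure(list(
    sigma_clin = sigma_clin, sigma_testretest = sigma_testretest,
    sigma_proc = proc$sd, sigma_series3 = s3$sd, sigma_cal = cal$sd,
    sigma_nonlin = nl$per_frequency, sigma_nonlin_mean = nl$mean,
    sigma_gain = sigma_gain, sigma_noise = sigma_noise,
    sigma_pop = pop$sd, sigma_proc_cal = pc$sd,
    sigma_pop_asc = sigma_pop_asc, clamped = clamped
  ), class = "error_budget")
}

#' @export
print.error_budget <- function(x, digits = 2, ...) {
  cat("Measurement-error budget (dB):\n")
  fmt <- function(v) format(round_half_up(v, digits), nsmall = digits)
  cat(sprintf("  clinical single measurement  sigma_clin     %s\n",
              fmt(x$sigma_clin)))
  cat(sprintf("  self-adjustment procedure    sigma_proc     %s\n",
              fmt(x$sigma_proc)))
  cat(sprintf("  home-series total            sigma_(iii)    %s\n",
              fmt(x$sigma_series3)))
  cat(sprintf("  calibration                  sigma_cal      %s\n",
              fmt(x$sigma_cal)))
  cat(sprintf("  nonlinearity (mean, ex 1kHz) sigma_nonlin   %s\n",
              fmt(x$sigma_nonlin_mean)))
  for (f in names(x$sigma_nonlin))
    cat(sprintf("    %6s Hz                                  %s%s\n", f,
                fmt(x$sigma_nonlin[[f]]),
                if (isTRUE(x$clamped[[paste0("sigma_nonlin_", f)]]))
                  " (clamped)" else ""))
  cat(sprintf("  reference population         sigma_pop      %s\n",
              fmt(x$sigma_pop)))
  cat(sprintf("  calibration task             sigma_proc_cal %s\n",
              fmt(x$sigma_proc_cal)))
  cat(sprintf("  gain                         sigma_gain     %s\n",
              fmt(x$sigma_gain)))
  cat(sprintf("  background noise             sigma_noise    %s\n",
              fmt(x$sigma_noise)))
  invisible(x)
}

#' Error budget as a tidy data frame
#'
#' @param budget an `error_budget` from [decompose()].
#' @return data frame with columns `component`, `value_db`, `clamped`,
#'   `provenance`.
#' @export
budget_as_data_frame <- function(budget) {
  cl <- function(name) isTRUE(budget$clamped[[name]])
  rows <- list(
    c("sigma_testretest", budget$sigma_testretest, FALSE, "adopted literature test-retest SD"),
    c("sigma_clin", budget$sigma_clin, FALSE, "test-retest SD / sqrt(2)"),
    c("sigma_proc", budget$sigma_proc, cl("sigma_proc"), "supervised-pairing total minus clinical"),
    c("sigma_series3", budget$sigma_series3, cl("sigma_series3"), "home-pairing total minus clinical"),
    c("sigma_cal", budget$sigma_cal, cl("sigma_cal"), "home vs supervised pairing at 1 kHz"),
    c("sigma_nonlin_mean", budget$sigma_nonlin_mean, any(budget$clamped[grepl("nonlin", names(budget$clamped))]), "mean over non-calibration frequencies"),
    c("sigma_pop", budget$sigma_pop, cl("sigma_pop"), "reference population minus clinical"),
    c("sigma_proc_cal", budget$sigma_proc_cal, cl("sigma_proc_cal"), "calibration minus population"),
    c("sigma_gain", budget$sigma_gain, FALSE, "set to 0: negligible by design"),
    c("sigma_noise", budget$sigma_noise, FALSE, "set to 0: negligible in quiet conditions")
  )
  for (f in names(budget$sigma_nonlin))
    rows[[length(rows) + 1]] <-
      c(paste0("sigma_nonlin_", f), budget$sigma_nonlin[[f]],
        cl(paste0("sigma_nonlin_", f)), "home pairing minus supervised and calibration")
  out <- data.frame(component = vapply(rows, `[[`, "", 1),
                    value_db = as.numeric(vapply(rows, `[[`, "", 2)),
                    clamped = as.logical(vapply(rows, `[[`, "", 3)),
                    provenance = vapply(rows, `[[`, "", 4))
  rownames(out) <- NULL
  out
}
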