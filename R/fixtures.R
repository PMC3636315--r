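# Packaged reference fixtures: the validation study's published
# between-series difference SDs and the literature compilation of clinical
# test-retest SDs. Both ship as plain CSV under extdata so the reference
# error budget can be recomputed without external input.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "webaudiometry")
  if (p == "") p <- file.path("inst", "extdata", file)  # during development
  if (!file.exists(p)) data_error("packaged fixture '%s' not found", file)
  p
}

#' Published between-series difference SDs
#'
#' The per-stratum SDs of the threshold differences observed in the
#' validation study: clinical vs supervised self-test (`"1v2"`) and
#' clinical vs home self-test (`"1v3"`), per frequency plus the pooled
#' `"total"` and per-ear `"mean"` strata.
#'
#' @return a [difference_sd_table()].
#' @export
reference_diff_table <- function() {
  d <- utils::read.csv(fixture_path("table1_sigma.csv"),
                       colClasses = c("character", "character", "numeric"))
  difference_sd_table(d$pairing, d$stratum, d$sigma)
}

#' Literature test-retest SD compilation
#'
#' Published SDs of the clinical hearing threshold in test-retest
#' examinations (supra-aural and in-ear headphones, three age groups), per
#' frequency; missing cells are `NA`.
#'
#' @return data frame with columns `study`, `series`, `n`, `f250` ...
#'   `f8000`.
#' @export
reference_testretest_table <- function() {
  utils::read.csv(fixture_path("table3_testretest.csv"),
                  colClasses = c("character", "character", "integer",
                                 rep("numeric", 6)))
}

#' Error budget recomputed from the packaged reference fixtures
#'
#' Runs the full decomposition chain on the packaged difference-SD table
#' and literature test-retest compilation, with the reference-population
#' ascending SD at its literature value of 5.6 dB. This is the budget the
#' decomposition is validated against.
#'
#' @param sigma_pop_asc literature SD of ascending-method thresholds among
#'   young normal-hearing subjects, dB.
#' @return an `error_budget`, see [decompose()].
#' @export
reference_budget <- function(sigma_pop_asc = 5.6) {
  decompose(reference_diff_table(),
            testretest_table = reference_testretest_table(),
            sigma_pop_asc = sigma_pop_asc)
}
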