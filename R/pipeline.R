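# Reproducible experiment pipeline: structured config, simulation and
# analysis stages with CSV outputs and a run manifest.

.config_sections <- list(
  top = c("version", "master_seed", "cohort", "error_model", "procedures",
          "analysis", "screening"),
  cohort = c("n_subjects", "ears_per_subject", "stratum_proportions",
             "home_followup_fraction", "ear_correlation"),
  error_model = c("sigma_clin", "sigma_proc", "sigma_cal_task", "sigma_pop",
                  "sigma_nonlin", "sigma_gain", "noise_floor_db",
                  "quantization_step", "floor_dbrphl"),
  procedures = c("mode", "max_output", "aweight_sign", "listener",
                 "ascending", "calibration"),
  analysis = c("delta", "alpha", "sigma_pop_asc", "group_cutoff"),
  screening = c("single_freq_set", "single_cutoff", "multi_cutoff",
                "high_freq", "high_cutoff")
)

check_keys <- function(x, section) {
  extra <- setdiff(names(x), .config_sections[[section]])
  if (length(extra))
    config_error("unknown key(s) in %s: %s", section,
                 paste(extra, collapse = ", "))
}

#' Experiment configuration
#'
#' Validates and normalizes a configuration list (typically read from a
#' YAML file) into the typed specs used by the pipeline. A `version` field
#' is required and unknown keys are rejected.
#'
#' @param config named list, or path to a YAML file.
#' @return object of class `experiment_config` with elements `version`,
#'   `master_seed`, `cohort` ([cohort_spec()]), `error_model`
#'   ([error_model_spec()]), `procedures`, `analysis`, `screening`.
#' @export
experiment_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) config_error("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a list or a file path")
  check_keys(config, "top")
  if (is.null(config$version))
    config_error("config requires a 'version' field")

  norm <- function(section, default = list()) {
    x <- config[[section]] %||% default
    check_keys(x, section)
    x
  }
  coh <- norm("cohort")
  if (!is.null(coh$stratum_proportions))
    coh$stratum_proportions <- as.numeric(unlist(coh$stratum_proportions))
  err <- norm("error_model")
  if (!is.null(err$sigma_nonlin))
    err$sigma_nonlin <- unlist(err$sigma_nonlin)
  prc <- norm("procedures")
  ana <- norm("analysis")
  scr <- norm("screening")

  structure(list(
    version = config$version,
    master_seed = as.integer(config$master_seed %||% 1L),
    cohort = do.call(cohort_spec, coh),
    error_model = do.call(error_model_spec, err),
    procedures = list(mode = prc$mode %||% "reduced",
                      max_output = prc$max_output %||% 100,
                      aweight_sign = prc$aweight_sign %||% 1,
                      listener = prc$listener %||% list(),
                      ascending = prc$ascending %||% list(),
                      calibration = prc$calibration %||% list()),
    analysis = list(delta = ana$delta %||% 1, alpha = ana$alpha %||% 0.05,
                    sigma_pop_asc = ana$sigma_pop_asc %||% 5.6,
                    group_cutoff = ana$group_cutoff %||% 40),
    screening = do.call(screening_criterion, scr)
  ), class = "experiment_config")
}

write_csv_file <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}

#' Read a measurements CSV written by [run_simulate()]
#'
#' @param path CSV path.
#' @return measurement data frame.
#' @export
read_measurements <- function(path) {
  d <- utils::read.csv(path)
  need <- c("subject_id", "ear", "series", "frequency_hz", "level_db",
            "no_response")
  if (!all(need %in% names(d)))
    data_error("measurements file lacks columns: %s",
               paste(setdiff(need, names(d)), collapse = ", "))
  d$no_response <- as.logical(d$no_response)
  d
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass_recursive(config)), tmp)
  unname(tools::md5sum(tmp))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Simulate the study and write its data files
#'
#' Writes `truth.csv` (latent audiograms) and `measurements.csv` (all three
#' series; series 3 only for the home follow-up subset) plus a
#' `manifest.json` with the config hash, package version, seed and file
#' checksums. Re-running with the same config yields identical checksums.
#'
#' @param config an [experiment_config()], list, or YAML path.
#' @param output_dir output directory (created if needed).
#' @return invisibly, a list with `truth`, `measurements`, `paths`,
#'   `manifest`.
#' @export
run_simulate <- function(config = experiment_config(list(version = 1)),
                         output_dir = ".") {
  if (!inherits(config, "experiment_config")) config <- experiment_config(config)
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    config_error("cannot create output directory '%s'", output_dir)

  study <- simulate_study(config$cohort, config$error_model,
                          seed = config$master_seed,
                          mode = config$procedures$mode,
                          max_output = config$procedures$max_output)

  paths <- c(truth = file.path(output_dir, "truth.csv"),
             measurements = file.path(output_dir, "measurements.csv"))
  write_csv_file(study$truth[, c("subject_id", "ear", "frequency_hz",
                                 "true_db")], paths["truth"])
  write_csv_file(study$measurements, paths["measurements"])

  manifest <- list(
    package_version = as.character(utils::packageVersion("webaudiometry")),
    config_hash = config_hash(config),
    master_seed = config$master_seed,
    checksums = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                        names(paths))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(truth = study$truth, measurements = study$measurements,
                 followup_subjects = study$followup_subjects,
                 paths = c(paths, manifest = manifest_path),
                 manifest = manifest))
}

#' Analyze measurements: agreement tables and screening
#'
#' Computes the agreement summaries for the pairings (1,2) and, when
#' series 3 is present, (1,3), plus the screening scores of each web series
#' against the clinical series.
#'
#' @param measurements measurement data frame or CSV path.
#' @param config an [experiment_config()], list, or YAML path.
#' @param output_dir optional; when given, writes `agreement.csv` and
#'   `screening.csv` there.
#' @return list with `agreement` (named by pairing), `screening` (data
#'   frame).
#' @export
run_analyze <- function(measurements,
                        config = experiment_config(list(version = 1)),
                        output_dir = NULL) {
  if (!inherits(config, "experiment_config")) config <- experiment_config(config)
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  series_present <- sort(unique(measurements$series))
  if (length(series_present) < 2)
    data_error("need at least two series to analyze")

  grid <- sort(unique(measurements$frequency_hz))
  pairings <- list()
  if (all(c(1, 2) %in% series_present)) pairings[["1v2"]] <- c(1, 2)
  if (all(c(1, 3) %in% series_present)) pairings[["1v3"]] <- c(1, 3)
  if (length(pairings) == 0) data_error("no clinical-vs-web pairing available")

  agreement <- lapply(pairings, function(p)
    agreement_table(stratify(measurements, p, grid,
                             group_cutoff = config$analysis$group_cutoff),
                    delta = config$analysis$delta,
                    alpha = config$analysis$alpha))

  screening <- do.call(rbind, lapply(
    intersect(c(2, 3), series_present), function(s)
      screen_series(measurements, s, 1, config$screening,
                    config$analysis$alpha)))

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir))
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    agr <- do.call(rbind, Map(function(tbl, nm)
      cbind(pairing = nm, tbl), agreement, names(agreement)))
    write_csv_file(agr, file.path(output_dir, "agreement.csv"))
    if (!is.null(screening))
      write_csv_file(screening, file.path(output_dir, "screening.csv"))
  }
  list(agreement = agreement, screening = screening)
}

#' Decompose an agreement result into an error budget
#'
#' @param agreement either the `agreement` list from [run_analyze()] (with
#'   both pairings), or a [difference_sd_table()].
#' @param testretest_table literature test-retest table; defaults to the
#'   packaged compilation.
#' @param sigma_pop_asc reference-population ascending SD, dB.
#' @param sigma_testretest optional direct override of the test-retest SD.
#' @param output_dir optional; when given, writes `error_budget.csv`.
#' @param grid frequency grid.
#' @return an `error_budget`, see [decompose()].
#' @export
run_decompose <- function(agreement, testretest_table = NULL,
                          sigma_pop_asc = 5.6, sigma_testretest = NULL,
                          output_dir = NULL, grid = default_grid()) {
  tbl <- if (inherits(agreement, "difference_sd_table")) agreement
         else {
           if (!all(c("1v2", "1v3") %in% names(agreement)))
             data_error("decomposition needs both pairings (1v2 and 1v3)")
           diff_table_from_agreement(agreement[["1v2"]], agreement[["1v3"]],
                                     grid)
         }
  if (is.null(testretest_table) && is.null(sigma_testretest))
    testretest_table <- reference_testretest_table()
  budget <- decompose(tbl, testretest_table = testretest_table,
                      sigma_testretest = sigma_testretest,
                      sigma_pop_asc = sigma_pop_asc, grid = grid)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir))
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_file(budget_as_data_frame(budget),
                   file.path(output_dir, "error_budget.csv"))
  }
  budget
}
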