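# Synthetic cohort: latent audiograms, device setups and the three
# measurement series of the validation study design.

#' Default audiometric frequency grid
#'
#' The six octave frequencies tested in all three series.
#'
#' @return numeric vector `c(250, 500, 1000, 2000, 4000, 8000)` Hz.
#' @export
default_grid <- function() c(250, 500, 1000, 2000, 4000, 8000)

validate_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 1 || any(grid <= 0))
    config_error("frequency grid must be positive numbers")
  if (is.unsorted(grid, strictly = TRUE))
    config_error("frequency grid must be strictly increasing")
  grid
}

#' Cohort specification
#'
#' Describes the study cohort: number of subjects, ears per subject, the
#' hearing-loss stratum mix and the fraction of subjects who complete the
#' unsupervised home series. Defaults reproduce the validation study's
#' cohort: 51 subjects, 102 ears split 45/17/31/9 across the strata
#' (mean threshold <=25, (25,40), [40,70), >=70 dBHL), 37 of 51 subjects
#' retested at home.
#'
#' @param n_subjects number of subjects.
#' @param ears_per_subject ears tested per subject.
#' @param stratum_proportions 4 fractions for the hearing-loss strata,
#'   summing to 1.
#' @param home_followup_fraction fraction of subjects completing series 3.
#' @param ear_correlation correlation of the two ears' audiogram shape
#'   deviations within a subject (0 = independent ears).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 51,
                        ears_per_subject = 2,
                        stratum_proportions = c(45, 17, 31, 9) / 102,
                        home_followup_fraction = 37 / 51,
                        ear_correlation = 0) {
  if (!is.numeric(n_subjects) || n_subjects <= 0 || n_subjects != round(n_subjects))
    config_error("n_subjects must be a positive integer")
  if (length(stratum_proportions) != 4 || any(stratum_proportions < 0))
    config_error("stratum_proportions must be 4 nonnegative fractions")
  if (abs(sum(stratum_proportions) - 1) > 1e-9)
    config_error("stratum_proportions must sum to 1 (got %.12f)",
                 sum(stratum_proportions))
  if (home_followup_fraction < 0 || home_followup_fraction > 1)
    config_error("home_followup_fraction must lie in [0, 1]")
  if (abs(ear_correlation) > 1)
    config_error("ear_correlation must lie in [-1, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 ears_per_subject = as.integer(ears_per_subject),
                 stratum_proportions = stratum_proportions,
                 home_followup_fraction = home_followup_fraction,
                 ear_correlation = ear_correlation),
            class = "cohort_spec")
}

#' Additive measurement-error model specification
#'
#' Standard deviations (dB) of the independent Gaussian error components of
#' the three series, plus the level grid conventions. Defaults are the
#' components estimated for the web-test design: single clinical measurement
#' 4.25 dB, self-adjustment procedure 6.64 dB, calibration-task 5.00 dB,
#' reference-person population spread 3.65 dB, frequency-nonlinearity SDs
#' peaking at 7.28 dB at 250 Hz and zero at the 1 kHz calibration frequency,
#' negligible gain error and background noise, a 5 dB attenuator step and a
#' 0 dBRP-HL floor on web-test levels.
#'
#' @param sigma_clin SD of a single clinical threshold measurement, dB.
#' @param sigma_proc SD of the web self-adjustment procedure, dB.
#' @param sigma_cal_task SD of one reference-person calibration task, dB.
#' @param sigma_pop SD of reference persons' true 1 kHz thresholds, dB.
#' @param sigma_nonlin named numeric: per-frequency SD of the frequency
#'   nonlinearity (RETSPL spread + sound-card response), dB; must be 0 at
#'   the 1 kHz calibration frequency.
#' @param sigma_gain SD of the gain error, dB (default 0: negligible).
#' @param noise_floor_db background-noise masking floor in dB, or `NULL`
#'   for off (default: negligible in quiet conditions).
#' @param quantization_step attenuator step, dB; 0 disables quantization.
#' @param floor_dbrphl lower bound of the web-test scale (0 dBRP-HL).
#' @return object of class `error_model_spec`.
#' @export
error_model_spec <- function(sigma_clin = 4.25,
                             sigma_proc = 6.64,
                             sigma_cal_task = 5.00,
                             sigma_pop = 3.65,
                             sigma_nonlin = c("250" = 7.28, "500" = 4.31,
                                              "1000" = 0, "2000" = 4.35,
                                              "4000" = 4.32, "8000" = 0),
                             sigma_gain = 0,
                             noise_floor_db = NULL,
                             quantization_step = 5,
                             floor_dbrphl = 0) {
  sds <- c(sigma_clin, sigma_proc, sigma_cal_task, sigma_pop,
           sigma_gain, sigma_nonlin)
  if (any(!is.finite(sds)) || any(sds < 0))
    config_error("all error-component SDs must be finite and >= 0")
  if (is.null(names(sigma_nonlin)) || any(names(sigma_nonlin) == ""))
    config_error("sigma_nonlin must be named by frequency in Hz")
  if ("1000" %in% names(sigma_nonlin) && sigma_nonlin[["1000"]] != 0)
    config_error("sigma_nonlin must be 0 at the 1 kHz calibration frequency")
  structure(list(sigma_clin = sigma_clin, sigma_proc = sigma_proc,
                 sigma_cal_task = sigma_cal_task, sigma_pop = sigma_pop,
                 sigma_nonlin = sigma_nonlin, sigma_gain = sigma_gain,
                 noise_floor_db = noise_floor_db,
                 quantization_step = quantization_step,
                 floor_dbrphl = floor_dbrphl),
            class = "error_model_spec")
}

nonlin_sd_at <- function(spec, frequency) {
  key <- as.character(frequency)
  if (key %in% names(spec$sigma_nonlin)) spec$sigma_nonlin[[key]] else 0
}

# Stratum bands in dBHL for the mean threshold of an ear. The top band is
# open-ended; 100 dB keeps means below the audiometer's maximum output.
.stratum_bands <- list(c(-10, 25), c(25, 40), c(40, 70), c(70, 100))

#' Generate latent true audiograms for a cohort
#'
#' Draws one real-valued (unquantized) audiogram per ear. Ears are assigned
#' to hearing-loss strata with exact largest-remainder counts; within a
#' stratum the ear's mean threshold is uniform over the stratum band, and
#' per-frequency thresholds add a linear slope across the grid (total span
#' uniform in +/-10 dB) plus independent N(0, 3 dB) jitter, centered so the
#' ear's mean threshold equals its stratum draw, then clipped to
#' [-10, 120] dBHL.
#'
#' @param spec a [cohort_spec()].
#' @param grid frequency grid in Hz.
#' @param seed integer seed; output is deterministic given the seed.
#' @return data frame with columns `subject_id`, `ear`, `stratum`,
#'   `frequency_hz`, `true_db` (one row per ear x frequency).
#' @export
generate_cohort <- function(spec = cohort_spec(), grid = default_grid(),
                            seed = 1) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_grid(grid)
  set.seed(substream_seed(seed, "cohort"))

  n_ears <- spec$n_subjects * spec$ears_per_subject
  counts <- apportion(n_ears, spec$stratum_proportions)
  strata <- sample(rep(seq_len(4), counts))

  ears <- if (spec$ears_per_subject == 2) c("left", "right") else
    paste0("ear", seq_len(spec$ears_per_subject))
  idx <- expand.grid(ear = ears, subject_id = seq_len(spec$n_subjects),
                     stringsAsFactors = FALSE)[, c(2, 1)]

  k <- length(grid)
  pos <- seq(-0.5, 0.5, length.out = k)  # centered grid position for slope
  rho <- spec$ear_correlation

  lo <- vapply(.stratum_bands, `[`, numeric(1), 1)[strata]
  hi <- vapply(.stratum_bands, `[`, numeric(1), 2)[strata]
  mu <- runif(n_ears, lo, hi)
  slope_span <- runif(n_ears, -10, 10)
  dev <- slope_span %o% pos + matrix(rnorm(n_ears * k, 0, 3), n_ears, k)
  # optional within-subject shape correlation between the two ears
  if (rho != 0 && spec$ears_per_subject == 2) {
    even <- seq(2, n_ears, by = 2)
    dev[even, ] <- rho * dev[even - 1, ] + sqrt(1 - rho^2) * dev[even, ]
  }
  # center deviations so the ear's mean threshold is its stratum draw,
  # keeping stratum membership exact
  dev <- dev - rowMeans(dev)
  thr <- pmin(pmax(mu + dev, -10), 120)

  truth <- data.frame(
    subject_id = rep(idx$subject_id, each = k),
    ear = rep(idx$ear, each = k),
    stratum = rep(strata, each = k),
    frequency_hz = rep(grid, n_ears),
    true_db = as.vector(t(thr)))
  rownames(truth) <- NULL
  truth
}

#' Generate a home test-station device setup
#'
#' Realizes one station's systematic offsets from the error model: the
#' calibration offset is the sum of a reference-person draw N(0, sigma_pop)
#' and a calibration-task draw N(0, sigma_cal_task); per-frequency
#' nonlinearity offsets are N(0, sigma_nonlin(f)) with exactly 0 at the
#' 1 kHz calibration frequency; the gain offset is N(0, sigma_gain).
#'
#' @param spec an [error_model_spec()].
#' @param grid frequency grid in Hz.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param device_id identifier stored on the setup.
#' @return object of class `device_setup` with fields `device_id`,
#'   `calibration_offset`, `nonlin_offsets` (named by frequency),
#'   `gain_offset`, `noise_floor_db`.
#' @export
generate_device <- function(spec = error_model_spec(), grid = default_grid(),
                            seed = NULL, device_id = "device1") {
  if (!inherits(spec, "error_model_spec")) spec <- do.call(error_model_spec, spec)
  validate_grid(grid)
  if (!is.null(seed)) set.seed(substream_seed(seed, "devices"))
  nl_sd <- vapply(grid, function(f) nonlin_sd_at(spec, f), numeric(1))
  nl <- rnorm(length(grid), 0, nl_sd)
  nl[grid == 1000] <- 0
  names(nl) <- as.character(grid)
  structure(list(
    device_id = device_id,
    calibration_offset = rnorm(1, 0, spec$sigma_pop) +
      rnorm(1, 0, spec$sigma_cal_task),
    nonlin_offsets = nl,
    gain_offset = rnorm(1, 0, spec$sigma_gain),
    noise_floor_db = spec$noise_floor_db
  ), class = "device_setup")
}

#' Generate one device per subject
#'
#' @param spec an [error_model_spec()].
#' @param subject_ids subject identifiers; one device is generated per id.
#' @param grid frequency grid.
#' @param seed integer seed for the device substream.
#' @return named list of `device_setup`, keyed by subject id.
#' @export
generate_devices <- function(spec = error_model_spec(), subject_ids,
                             grid = default_grid(), seed = 1) {
  set.seed(substream_seed(seed, "devices"))
  devs <- lapply(subject_ids, function(id)
    generate_device(spec, grid, seed = NULL,
                    device_id = paste0("device_", id)))
  names(devs) <- as.character(subject_ids)
  devs
}

# Total systematic device offset at one frequency.
device_offset <- function(device, frequency) {
  if (is.null(device)) return(0)
  device$calibration_offset + device$nonlin_offsets[[as.character(frequency)]] +
    device$gain_offset
}

zero_device <- function(grid = default_grid(), device_id = "shared") {
  nl <- stats::setNames(rep(0, length(grid)), as.character(grid))
  structure(list(device_id = device_id, calibration_offset = 0,
                 nonlin_offsets = nl, gain_offset = 0,
                 noise_floor_db = NULL),
            class = "device_setup")
}

#' Simulate one measurement series
#'
#' Produces observed thresholds for every ear x frequency of the latent
#' cohort. In `reduced` mode the observation is the additive model
#' `quantize(true + procedure error + device offsets)`, with the procedure
#' error N(0, sigma_clin) for series 1 and N(0, sigma_proc) for series 2-3,
#' followed by the 0 dBRP-HL floor for series 2-3. In `behavioral` mode the
#' level is produced by the threshold procedures themselves: the clinical
#' ascending method for series 1 and the self-adjustment task for series
#' 2-3. Levels above `max_output` are recorded as no-response.
#'
#' Series 2 runs on a single shared, supervised station whose offsets
#' default to zero (its constant calibration error moves the mean
#' difference, not the SD); series 3 requires one device per subject.
#'
#' @param truth cohort data frame from [generate_cohort()].
#' @param spec an [error_model_spec()].
#' @param series_id 1, 2 or 3.
#' @param devices for series 3, a named list of `device_setup` keyed by
#'   subject id (see [generate_devices()]); for series 2 optionally a single
#'   shared `device_setup`.
#' @param mode `"reduced"` (additive model) or `"behavioral"` (procedure
#'   simulation).
#' @param seed integer master seed; the series uses its own substream.
#' @param max_output maximum presentable level in dB (default 100).
#' @param listener_cfg,ascending_cfg behavioral-mode configurations, see
#'   [listener()] and [ascending_config()].
#' @return data frame with columns `subject_id`, `ear`, `series`,
#'   `frequency_hz`, `level_db`, `no_response`.
#' @export
simulate_series <- function(truth, spec = error_model_spec(), series_id,
                            devices = NULL, mode = c("reduced", "behavioral"),
                            seed = 1, max_output = 100,
                            listener_cfg = NULL, ascending_cfg = NULL) {
  mode <- match.arg(mode)
  if (!inherits(spec, "error_model_spec")) spec <- do.call(error_model_spec, spec)
  if (!series_id %in% 1:3) config_error("series_id must be 1, 2 or 3")
  set.seed(substream_seed(seed, paste0("series", series_id)))

  n <- nrow(truth)
  is_web <- series_id >= 2

  # resolve per-row device offsets
  if (series_id == 3) {
    if (is.null(devices))
      config_error("series 3 requires one device per subject")
    subj <- as.character(truth$subject_id)
    miss <- setdiff(unique(subj), names(devices))
    if (length(miss))
      config_error("missing device for subject(s): %s",
                   paste(miss, collapse = ", "))
    flat <- vapply(devices, function(d) d$calibration_offset + d$gain_offset,
                   numeric(1))
    nonlin <- t(vapply(devices, function(d) d$nonlin_offsets,
                       numeric(length(devices[[1]]$nonlin_offsets))))
    offs <- flat[subj] +
      nonlin[cbind(match(subj, names(devices)),
                   match(as.character(truth$frequency_hz),
                         colnames(nonlin)))]
  } else if (series_id == 2) {
    shared <- if (is.null(devices)) zero_device(sort(unique(truth$frequency_hz)))
              else if (inherits(devices, "device_setup")) devices
              else config_error("series 2 takes a single shared device")
    offs <- vapply(truth$frequency_hz, function(f)
      device_offset(shared, f), numeric(1))
  } else {
    offs <- rep(0, n)
  }

  if (mode == "reduced") {
    sd_proc <- if (series_id == 1) spec$sigma_clin else spec$sigma_proc
    raw <- truth$true_db + stats::rnorm(n, 0, sd_proc) + offs
  } else {
    if (series_id == 1) {
      lcfg <- listener_cfg %||% listener(0)
      acfg <- ascending_cfg %||% ascending_config(max_output = max_output)
      raw <- vapply(seq_len(n), function(i) {
        l <- lcfg; l$true_threshold <- truth$true_db[i]
        ascending_threshold(l, acfg)
      }, numeric(1))
    } else {
      raw <- self_adjust_threshold(truth$true_db + offs,
                                   sigma_adjust = spec$sigma_proc,
                                   step = 0)  # quantized below
    }
  }

  # background-noise masking floor (off by default)
  nf <- spec$noise_floor_db
  if (!is.null(nf) && is_web) raw <- pmax(raw, nf)

  level <- quantize(raw, spec$quantization_step)
  if (is_web) level <- pmax(level, spec$floor_dbrphl)

  no_resp <- is.na(level) | level > max_output
  level[no_resp] <- NA_real_

  data.frame(subject_id = truth$subject_id, ear = truth$ear,
             series = series_id, frequency_hz = truth$frequency_hz,
             level_db = level, no_response = no_resp)
}

#' Simulate the full three-series study
#'
#' Convenience wrapper: generates the cohort, the shared supervised station
#' (offsets zero), one home device per follow-up subject, and the three
#' measurement series, restricting series 3 to a random follow-up subset of
#' subjects.
#'
#' @param cohort a [cohort_spec()].
#' @param errors an [error_model_spec()].
#' @param grid frequency grid.
#' @param seed master seed; all stages use named substreams of it.
#' @param mode `"reduced"` or `"behavioral"`.
#' @param max_output maximum presentable level, dB.
#' @return list with elements `truth` (cohort data frame), `measurements`
#'   (all series row-bound), `devices`, `followup_subjects`.
#' @export
simulate_study <- function(cohort = cohort_spec(), errors = error_model_spec(),
                           grid = default_grid(), seed = 1,
                           mode = "reduced", max_output = 100) {
  if (!inherits(cohort, "cohort_spec")) cohort <- do.call(cohort_spec, cohort)
  truth <- generate_cohort(cohort, grid, seed)

  subjects <- unique(truth$subject_id)
  n_follow <- round(cohort$home_followup_fraction * length(subjects))
  set.seed(substream_seed(seed, "followup"))
  followup <- sort(sample(subjects, n_follow))

  devices <- generate_devices(errors, followup, grid, seed)
  truth3 <- truth[truth$subject_id %in% followup, ]

  s1 <- simulate_series(truth, errors, 1, mode = mode, seed = seed,
                        max_output = max_output)
  s2 <- simulate_series(truth, errors, 2, mode = mode, seed = seed,
                        max_output = max_output)
  s3 <- simulate_series(truth3, errors, 3, devices = devices, mode = mode,
                        seed = seed, max_output = max_output)

  list(truth = truth, measurements = rbind(s1, s2, s3),
       devices = devices, followup_subjects = followup)
}
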