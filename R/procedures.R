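# Behavioral models of the three threshold procedures: the clinical
# ascending method, the web self-adjustment task, and the paired-tone
# reference-person calibration, plus the A-weighting reference model.

#' Psychometric listener model
#'
#' A cumulative-Gaussian detection model: the probability of responding to a
#' tone at `level` is `guess + (1 - guess - lapse) * pnorm((level -
#' threshold) / slope)`. The slope is the SD of the underlying Gaussian in
#' dB; as it tends to 0 the listener becomes a deterministic step detector.
#'
#' @param true_threshold threshold in dBHL at the tested frequency.
#' @param slope psychometric slope in dB (> 0, or 0 for a step listener).
#' @param lapse probability of missing a clearly audible tone (<= 0.1).
#' @param guess probability of responding to an inaudible tone (<= 0.1).
#' @return object of class `listener`.
#' @export
listener <- function(true_threshold, slope = 5, lapse = 0.02, guess = 0.02) {
  if (slope < 0) config_error("psychometric slope must be >= 0")
  if (lapse < 0 || lapse > 0.1 || guess < 0 || guess > 0.1)
    config_error("lapse and guess rates must lie in [0, 0.1]")
  structure(list(true_threshold = true_threshold, slope = slope,
                 lapse = lapse, guess = guess), class = "listener")
}

#' Probability of a response at a presentation level
#'
#' @param l a [listener()].
#' @param level presentation level(s) in dB.
#' @return response probabilities, monotone nondecreasing in level.
#' @export
response_probability <- function(l, level) {
  base <- if (l$slope == 0) as.numeric(level >= l$true_threshold)
          else stats::pnorm((level - l$true_threshold) / l$slope)
  l$guess + (1 - l$guess - l$lapse) * base
}

#' Simulate yes/no responses to tone presentations
#'
#' @param l a [listener()].
#' @param level presentation level(s) in dB.
#' @return logical vector of Bernoulli responses (uses the current RNG
#'   state; seed with `set.seed()` for reproducibility).
#' @export
psychometric_response <- function(l, level) {
  stats::runif(length(level)) < response_probability(l, level)
}

#' Ascending-method configuration
#'
#' Bracketing parameters of the clinical threshold search: descend in 10 dB
#' steps after responses, then ascend in 5 dB steps; the threshold is the
#' lowest level with responses on at least half of the ascending runs, with
#' a minimum of two responses at that level.
#'
#' @param start_level first presentation level, dB.
#' @param descend_step,ascend_step step sizes in dB.
#' @param min_responses minimum responses required at the threshold level.
#' @param max_trials maximum number of ascending runs before giving up.
#' @param max_output maximum presentable level, dB.
#' @param min_level attenuator floor, dB.
#' @return object of class `ascending_config`.
#' @export
ascending_config <- function(start_level = 60, descend_step = 10,
                             ascend_step = 5, min_responses = 2,
                             max_trials = 30, max_output = 100,
                             min_level = -10) {
  if (descend_step <= 0 || ascend_step <= 0)
    config_error("step sizes must be positive")
  if (min_responses < 2) config_error("min_responses must be >= 2")
  structure(list(start_level = start_level, descend_step = descend_step,
                 ascend_step = ascend_step, min_responses = min_responses,
                 max_trials = max_trials, max_output = max_output,
                 min_level = min_level), class = "ascending_config")
}

#' Clinical ascending-method threshold
#'
#' Simulates the ISO-style bracketing procedure on a psychometric listener:
#' present at the start level (ascending if inaudible), descend in 10 dB
#' steps while responses occur, then run ascending series in 5 dB steps.
#' After each ascending response the level drops 10 dB and a new ascent
#' begins. The procedure stops at the lowest level that collected responses
#' on at least half of the ascending runs with at least `min_responses`
#' responses.
#'
#' @param l a [listener()].
#' @param cfg an [ascending_config()].
#' @return threshold in dB, or `NA` with attribute `reason`
#'   (`"above_max_output"` or `"max_trials"`) when no threshold could be
#'   established.
#' @export
ascending_threshold <- function(l, cfg = ascending_config()) {
  present <- function(level) psychometric_response(l, level)

  lvl <- cfg$start_level
  # find an audible starting point
  while (!present(lvl)) {
    lvl <- lvl + cfg$descend_step
    if (lvl > cfg$max_output)
      return(structure(NA_real_, reason = "above_max_output"))
  }
  # initial wide descent to a miss
  while (lvl > cfg$min_level && present(lvl - cfg$descend_step))
    lvl <- lvl - cfg$descend_step
  miss_level <- lvl - cfg$descend_step

  counts <- new.env(parent = emptyenv())
  runs <- 0L
  repeat {
    runs <- runs + 1L
    if (runs > cfg$max_trials)
      return(structure(NA_real_, reason = "max_trials"))
    # one ascending run
    lvl <- max(miss_level, cfg$min_level - cfg$ascend_step) + cfg$ascend_step
    while (!present(lvl)) {
      lvl <- lvl + cfg$ascend_step
      if (lvl > cfg$max_output)
        return(structure(NA_real_, reason = "above_max_output"))
    }
    key <- as.character(lvl)
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    # threshold rule: lowest level with >= half of runs and >= min_responses
    lv <- as.numeric(ls(counts))
    cnt <- vapply(ls(counts), function(k) counts[[k]], integer(1))
    ok <- cnt >= cfg$min_responses & cnt >= runs / 2
    if (any(ok)) return(min(lv[ok]))
    miss_level <- lvl - cfg$descend_step
  }
}

#' Web self-adjustment threshold (method of adjustment)
#'
#' Models the subject moving a volume slider until the tone sits at the
#' verge of audibility: the returned level is the true threshold plus
#' N(0, sigma_adjust), quantized to the slider step. The adjustment SD is
#' configured directly (default 6.64 dB) rather than derived from the
#' psychometric slope, because the self-assessment difficulty it captures
#' is only observable in aggregate. The 0 dBRP-HL floor is applied by the
#' caller.
#'
#' @param threshold true threshold(s) in the test scale, dB.
#' @param sigma_adjust SD of the adjustment error, dB.
#' @param step slider step in dB (0 disables quantization).
#' @return adjusted level(s), dB.
#' @export
self_adjust_threshold <- function(threshold, sigma_adjust = 6.64, step = 5) {
  if (step < 0) config_error("slider step must be >= 0")
  quantize(threshold + stats::rnorm(length(threshold), 0, sigma_adjust), step)
}

#' Calibration-task configuration
#'
#' The paired-tone reference task: two tones 5 dB apart are alternated and
#' the reference person places the pair so that only the louder one is
#' audible, using a 1 dB slider; the pair midpoint defines 0 dBRP-HL. Six
#' single calibrations by three normal-hearing persons (two each) are
#' averaged into the station's calibration coefficient.
#'
#' @param pair_difference level difference of the two tones, dB.
#' @param slider_step slider resolution, dB.
#' @param n_repeats total number of single calibrations.
#' @param n_persons number of reference persons sharing the repeats.
#' @param sigma_task SD of one single calibration around the reference
#'   person's true threshold, dB.
#' @return object of class `calibration_config`.
#' @export
calibration_config <- function(pair_difference = 5, slider_step = 1,
                               n_repeats = 6, n_persons = 3,
                               sigma_task = 5.00) {
  if (pair_difference <= 0 || slider_step <= 0)
    config_error("pair_difference and slider_step must be positive")
  if (sigma_task < 0) config_error("sigma_task must be >= 0")
  structure(list(pair_difference = pair_difference, slider_step = slider_step,
                 n_repeats = n_repeats, n_persons = n_persons,
                 sigma_task = sigma_task), class = "calibration_config")
}

#' One single calibration by a reference person
#'
#' Returns the midpoint of the final tone pair: the reference person's true
#' threshold plus N(0, sigma_task), quantized at the slider step. The task
#' measures the reference person's threshold, not 0: a reference with a
#' nonzero threshold shifts the whole dBRP-HL scale by that amount.
#'
#' @param reference a [listener()] (only `true_threshold` is used) or a
#'   numeric threshold.
#' @param cfg a [calibration_config()].
#' @return adjusted mid-level in dB.
#' @export
calibration_task <- function(reference, cfg = calibration_config()) {
  thr <- if (inherits(reference, "listener")) reference$true_threshold
         else reference
  quantize(thr + stats::rnorm(1, 0, cfg$sigma_task), cfg$slider_step)
}

#' Station calibration coefficient
#'
#' Each reference person performs the single calibration
#' `round(n_repeats / #persons)` times; the calibration coefficient is the
#' arithmetic mean of all single calibrations.
#'
#' @param references list of [listener()]s or numeric thresholds.
#' @param cfg a [calibration_config()].
#' @return calibration coefficient in dB.
#' @export
calibrate_station <- function(references, cfg = calibration_config()) {
  if (length(references) == 0)
    config_error("at least one reference person is required")
  per <- max(1L, as.integer(round(cfg$n_repeats / length(references))))
  vals <- unlist(lapply(references, function(r)
    replicate(per, calibration_task(r, cfg))))
  mean(vals)
}

#' A-weighting gain
#'
#' Standard IEC 61672 A-weighting curve, normalized so that the gain at the
#' 1 kHz calibration frequency is exactly 0 dB.
#'
#' @param frequency frequency (or vector) in Hz, > 0.
#' @return gain A(f) in dB.
#' @export
#' @examples
#' a_weight(1000)  # 0
#' a_weight(250)   # about -8.7
a_weight <- function(frequency) {
  if (any(frequency <= 0)) domain_error("frequency must be positive")
  ra <- function(f) {
    f2 <- f^2
    (12194^2 * f2^2) /
      ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
  }
  20 * log10(ra(frequency) / ra(1000))
}

#' Reference levels across the frequency grid
#'
#' Extrapolates the 1 kHz calibration coefficient to the other test
#' frequencies with the A-weighting model: `reference(f) = cal - sign *
#' A(f)`. With the default sign (+1), frequencies the ear attenuates more
#' (negative A-weighting gain) receive a higher drive level. The direction
#' of the correction is configurable because only the use of an A-weighting
#' based model, not its orientation, is pinned by the test design.
#'
#' @param cal_coefficient calibration coefficient at 1 kHz, dB.
#' @param grid frequency grid in Hz.
#' @param aweight_sign +1 (default) or -1.
#' @return named numeric of reference levels, `reference(1000) ==
#'   cal_coefficient` exactly.
#' @export
reference_levels <- function(cal_coefficient, grid = default_grid(),
                             aweight_sign = 1) {
  validate_grid(grid)
  if (!aweight_sign %in% c(-1, 1)) config_error("aweight_sign must be +1 or -1")
  ref <- cal_coefficient - aweight_sign * a_weight(grid)
  names(ref) <- as.character(grid)
  ref
}
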