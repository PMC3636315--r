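# Noise-induced hearing-loss screening: the fixed criterion and its
# sensitivity/specificity against the clinical reference.

#' Screening criterion for noise-induced hearing loss
#'
#' The rule: positive when the threshold exceeds `single_cutoff` (30 dB) at
#' one of the speech frequencies 500/1000/2000 Hz, or exceeds
#' `multi_cutoff` (25 dB) at more than one of them, or exceeds
#' `high_cutoff` (50 dB) at the high-frequency notch target (4 kHz).
#' "Exceeds" is strict.
#'
#' @param single_freq_set speech frequencies in Hz.
#' @param single_cutoff single-frequency cutoff, dB.
#' @param multi_cutoff multi-frequency cutoff, dB.
#' @param high_freq high-frequency target, Hz.
#' @param high_cutoff high-frequency cutoff, dB.
#' @return object of class `screening_criterion`.
#' @export
screening_criterion <- function(single_freq_set = c(500, 1000, 2000),
                                single_cutoff = 30, multi_cutoff = 25,
                                high_freq = 4000, high_cutoff = 50) {
  if (single_cutoff <= 0 || multi_cutoff <= 0 || high_cutoff <= 0)
    config_error("cutoffs must be positive")
  if (multi_cutoff > single_cutoff)
    config_error("multi_cutoff must not exceed single_cutoff")
  structure(list(single_freq_set = single_freq_set,
                 single_cutoff = single_cutoff, multi_cutoff = multi_cutoff,
                 high_freq = high_freq, high_cutoff = high_cutoff),
            class = "screening_criterion")
}

#' Classify one audiogram by the screening criterion
#'
#' A no-response at a criterion frequency means the tone was inaudible at
#' maximum output, so it counts as exceeding every cutoff.
#'
#' @param thresholds named numeric, thresholds in dB keyed by frequency.
#' @param criterion a [screening_criterion()].
#' @param no_response optional named logical keyed by frequency.
#' @return `TRUE` if the audiogram is screen-positive.
#' @export
nihl_positive <- function(thresholds, criterion = screening_criterion(),
                          no_response = NULL) {
  get_thr <- function(f) {
    key <- as.character(f)
    nr <- !is.null(no_response) && key %in% names(no_response) &&
      isTRUE(no_response[[key]])
    if (nr) return(Inf)
    if (!key %in% names(thresholds) || is.na(thresholds[[key]]))
      data_error("missing threshold at criterion frequency %s Hz", key)
    thresholds[[key]]
  }
  speech <- vapply(criterion$single_freq_set, get_thr, numeric(1))
  high <- get_thr(criterion$high_freq)
  any(speech > criterion$single_cutoff) ||
    sum(speech > criterion$multi_cutoff) > 1 ||
    high > criterion$high_cutoff
}

#' Sensitivity and specificity with Wald intervals
#'
#' Scores test labels against reference labels. Confidence intervals are
#' Wald (`p +/- z sqrt(p(1-p)/n)`) truncated to `[0, 1]`; Wilson intervals
#' are available behind `method = "wilson"`.
#'
#' @param reference_labels logical vector, reference (clinical) calls.
#' @param test_labels logical vector, web-test calls.
#' @param alpha two-sided significance level.
#' @param method `"wald"` (default) or `"wilson"`.
#' @return list with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `sens_lo`,
#'   `sens_hi`, `specificity`, `spec_lo`, `spec_hi`; a rate with no
#'   eligible cases is `NA`.
#' @export
sens_spec <- function(reference_labels, test_labels, alpha = 0.05,
                      method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (length(reference_labels) != length(test_labels))
    data_error("label vectors must have equal length")
  tp <- sum(reference_labels & test_labels)
  fn <- sum(reference_labels & !test_labels)
  tn <- sum(!reference_labels & !test_labels)
  fp <- sum(!reference_labels & test_labels)

  ci <- function(k, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    p <- k / n
    z <- stats::qnorm(1 - alpha / 2)
    if (method == "wald") {
      half <- z * sqrt(p * (1 - p) / n)
      c(p, max(0, p - half), min(1, p + half))
    } else {
      w <- stats::prop.test(k, n, conf.level = 1 - alpha, correct = FALSE)
      c(p, w$conf.int[1], w$conf.int[2])
    }
  }
  se <- ci(tp, tp + fn)
  sp <- ci(tn, tn + fp)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = se[1], sens_lo = se[2], sens_hi = se[3],
       specificity = sp[1], spec_lo = sp[2], spec_hi = sp[3])
}

#' Screen a measurement series against the clinical reference
#'
#' Builds per-ear audiograms for the reference and test series, classifies
#' both with the criterion, and scores agreement. Only ears present in
#' both series with every criterion frequency resolved (a level or an
#' explicit no-response) are scored.
#'
#' @param measurements measurement data frame.
#' @param test_series series id of the web test (2 or 3).
#' @param reference_series series id of the reference (default 1).
#' @param criterion a [screening_criterion()].
#' @param alpha two-sided significance level.
#' @return data frame with one row of counts and rates, plus a `series`
#'   column.
#' @export
screen_series <- function(measurements, test_series, reference_series = 1,
                          criterion = screening_criterion(), alpha = 0.05) {
  ear_calls <- function(series_id) {
    d <- measurements[measurements$series == series_id, ]
    vapply(split(d, paste(d$subject_id, d$ear, sep = "|")), function(sub) {
      thr <- stats::setNames(sub$level_db, as.character(sub$frequency_hz))
      nr <- stats::setNames(sub$no_response, as.character(sub$frequency_hz))
      tryCatch(nihl_positive(thr, criterion, nr), error = function(e) NA)
    }, logical(1))
  }
  ref <- ear_calls(reference_series)
  tst <- ear_calls(test_series)
  shared <- intersect(names(ref), names(tst))
  ok <- shared[!is.na(ref[shared]) & !is.na(tst[shared])]
  res <- sens_spec(ref[ok], tst[ok], alpha)
  data.frame(series = test_series, n_ears = length(ok),
             tp = res$tp, fp = res$fp, tn = res$tn, fn = res$fn,
             sensitivity = res$sensitivity, sens_lo = res$sens_lo,
             sens_hi = res$sens_hi, specificity = res$specificity,
             spec_lo = res$spec_lo, spec_hi = res$spec_hi)
}
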