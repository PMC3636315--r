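test_that("psychometric response follows the cumulative-Gaussian model", {
  # step-function limits
  det <- step_listener(40)
  set.seed(1)
  expect_true(all(psychometric_response(det, rep(41, 50))))
  expect_false(any(psychometric_response(det, rep(39, 50))))

  # response rate at threshold is one half
  l <- listener(40, slope = 5, lapse = 0, guess = 0)
  set.seed(2)
  rate <- mean(psychometric_response(l, rep(40, 1e5)))
  expect_equal(rate, 0.5, tolerance = 0.02)

  # monotone nondecreasing in level
  probs <- response_probability(listener(40), seq(0, 100, 5))
  expect_true(all(diff(probs) >= 0))
})

test_that("ascending method matches the deterministic bracketing trace", {
  # step listener at 40 dB, start 60: descend 60/50/40 respond, miss at 30,
  # two ascending runs both end at 40 -> threshold 40
  set.seed(1)
  expect_equal(ascending_threshold(step_listener(40),
                                   ascending_config(start_level = 60)), 40)
  # start below threshold: initial ascent first
  set.seed(1)
  expect_equal(ascending_threshold(step_listener(40),
                                   ascending_config(start_level = 20)), 40)
  # threshold off the 5 dB grid resolves to the next step above
  set.seed(1)
  expect_equal(ascending_threshold(step_listener(42),
                                   ascending_config(start_level = 60)), 45)
  # unreachable threshold
  res <- ascending_threshold(step_listener(120),
                             ascending_config(start_level = 60,
                                              max_output = 100))
  expect_true(is.na(res))
  expect_equal(attr(res, "reason"), "above_max_output")
})

test_that("ascending-method estimates are monotone in listener sensitivity", {
  set.seed(3)
  thr <- vapply(c(10, 25, 40, 55, 70), function(t)
    ascending_threshold(step_listener(t), ascending_config()), numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("ascending-method spread matches clinical test-retest figures", {
  # with the default psychometric listener, the single-test SD should sit
  # in the 3-6 dB range implied by published test-retest data
  set.seed(4)
  reps <- replicate(1500, ascending_threshold(listener(40),
                                              ascending_config()))
  reps <- reps[!is.na(reps)]
  expect_gt(sd(reps), 3)
  expect_lt(sd(reps), 6)
  # the 2-response ascending rule sits a few dB above the p50 threshold,
  # never below it
  expect_gt(mean(reps), 40)
  expect_lt(mean(reps) - 40, 5)
})

test_that("self-adjustment quantizes and reproduces its configured SD", {
  set.seed(5)
  expect_equal(self_adjust_threshold(43, sigma_adjust = 0), 45)
  expect_equal(self_adjust_threshold(0, sigma_adjust = 0), 0)
  vals <- self_adjust_threshold(rep(40, 1e4), sigma_adjust = 6.64)
  expect_true(all(vals %% 5 == 0))
  expect_equal(sd(vals), 6.64, tolerance = 0.05)
  expect_lt(abs(mean(vals) - 40), 0.5)  # at most the quantization bias
})

test_that("calibration task measures the reference person's threshold", {
  quiet <- calibration_config(sigma_task = 0)
  set.seed(6)
  expect_equal(calibration_task(listener(0), quiet), 0)
  expect_equal(calibration_task(listener(7), quiet), 7)
  # task noise SD is reproduced
  vals <- replicate(1e4, calibration_task(listener(0),
                                          calibration_config(sigma_task = 5)))
  expect_equal(sd(vals), 5, tolerance = 0.03)
})

test_that("station calibration averages the single calibrations", {
  quiet <- calibration_config(sigma_task = 0)
  set.seed(7)
  expect_equal(calibrate_station(list(listener(0)), quiet), 0)
  expect_equal(calibrate_station(list(listener(0), listener(0), listener(0)),
                                 quiet), 0)
  expect_equal(calibrate_station(list(listener(-2), listener(0), listener(2)),
                                 quiet), 0)
  expect_error(calibrate_station(list(), quiet),
               class = "webaudiometry_config_error")

  # variance shrinks as 1/n_effective for i.i.d. references
  cfg2 <- calibration_config(sigma_task = 5, n_repeats = 2, n_persons = 1)
  cfg8 <- calibration_config(sigma_task = 5, n_repeats = 8, n_persons = 1)
  v2 <- var(replicate(3000, calibrate_station(list(listener(0)), cfg2)))
  v8 <- var(replicate(3000, calibrate_station(list(listener(0)), cfg8)))
  expect_equal(v2 / v8, 4, tolerance = 0.25)
})

test_that("A-weighting matches the standard closed form", {
  expect_equal(a_weight(1000), 0, tolerance = 1e-9)
  expect_equal(a_weight(250), -8.7, tolerance = 0.1)
  expect_equal(a_weight(8000), -1.1, tolerance = 0.1)
  # smooth on a 1 Hz grid (steepest near the low-frequency roll-off),
  # with a maximum near 2.5 kHz
  f <- seq(100, 10000, by = 1)
  expect_lt(max(abs(diff(a_weight(f)))), 0.2)
  expect_equal(f[which.max(a_weight(f))], 2500, tolerance = 0.2)
  expect_error(a_weight(-100), class = "webaudiometry_domain_error")
})

test_that("reference levels extrapolate the calibration coefficient", {
  ref <- reference_levels(0)
  expect_equal(ref[["1000"]], 0)
  expect_equal(ref[["250"]], 8.7, tolerance = 0.1)
  # additivity in the coefficient
  ref_c <- reference_levels(3.5)
  expect_equal(unname(ref_c - ref), rep(3.5, 6))
  # sign switch flips the correction
  ref_neg <- reference_levels(0, aweight_sign = -1)
  expect_equal(unname(ref_neg), -unname(ref))
})
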