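test_that("cohort stratum counts are exact and bands are respected", {
  truth <- generate_cohort(seed = 1)
  expect_equal(nrow(truth), 102 * 6)
  ear_means <- tapply(truth$true_db, paste(truth$subject_id, truth$ear), mean)
  counts <- table(cut(ear_means, c(-Inf, 25, 40, 70, Inf)))
  expect_equal(as.integer(counts), c(45, 17, 31, 9))

  # degenerate proportions: every ear in the no-loss band
  spec <- cohort_spec(n_subjects = 10, stratum_proportions = c(1, 0, 0, 0))
  t2 <- generate_cohort(spec, seed = 3)
  m2 <- tapply(t2$true_db, paste(t2$subject_id, t2$ear), mean)
  expect_true(all(m2 <= 25))

  expect_true(all(truth$true_db >= -10 & truth$true_db <= 120))
})

test_that("cohort generation is deterministic given the seed", {
  expect_identical(generate_cohort(seed = 42), generate_cohort(seed = 42))
  expect_false(identical(generate_cohort(seed = 42),
                         generate_cohort(seed = 43)))
})

test_that("cohort spec validation rejects bad configurations", {
  expect_error(cohort_spec(stratum_proportions = c(0.5, 0.5, 0.5, 0.5)),
               class = "webaudiometry_config_error")
  expect_error(cohort_spec(n_subjects = 0),
               class = "webaudiometry_config_error")
  expect_error(error_model_spec(sigma_proc = -1),
               class = "webaudiometry_config_error")
  expect_error(error_model_spec(sigma_nonlin = c("1000" = 2)),
               class = "webaudiometry_config_error")
})

test_that("device offsets realize the configured error components", {
  # degenerate spec: all offsets exactly zero
  d0 <- generate_device(zero_noise_spec(), seed = 1)
  expect_equal(d0$calibration_offset, 0)
  expect_equal(unname(d0$nonlin_offsets), rep(0, 6))
  expect_equal(d0$gain_offset, 0)

  # Monte-Carlo: calibration offset SD matches sqrt(pop^2 + cal_task^2)
  devs <- generate_devices(error_model_spec(), seq_len(10000), seed = 99)
  cal <- vapply(devs, `[[`, numeric(1), "calibration_offset")
  expect_equal(sd(cal), sqrt(3.65^2 + 5.00^2), tolerance = 0.02)

  # nonlinearity offset at the calibration frequency is identically zero
  nl1k <- vapply(devs, function(d) d$nonlin_offsets[["1000"]], numeric(1))
  expect_true(all(nl1k == 0))
})

test_that("reduced-mode series applies quantization, floor and no-response", {
  truth <- flat_truth(43, n_ears = 4)
  m3 <- simulate_series(truth, zero_noise_spec(), 3,
                        devices = generate_devices(zero_noise_spec(),
                                                   unique(truth$subject_id)),
                        seed = 1)
  expect_true(all(m3$level_db == 45))  # round-half-up of 43 on the 5 dB grid

  m2 <- simulate_series(flat_truth(-7, 2), zero_noise_spec(), 2, seed = 1)
  expect_true(all(m2$level_db == 0))   # floored at 0 dBRP-HL

  m1 <- simulate_series(flat_truth(-7, 2), zero_noise_spec(), 1, seed = 1)
  expect_true(all(m1$level_db == -5))  # clinical series is not floored

  # unreachable threshold: no response, level NA
  mh <- simulate_series(flat_truth(110, 2), zero_noise_spec(), 2, seed = 1)
  expect_true(all(mh$no_response))
  expect_true(all(is.na(mh$level_db)))

  # quantized outputs are multiples of the step
  stoch <- simulate_series(flat_truth(40, 20), error_model_spec(), 2, seed = 5)
  lv <- stoch$level_db[!stoch$no_response]
  expect_true(all(lv %% 5 == 0))
  expect_true(all(lv >= 0))
})

test_that("series 3 without per-subject devices is a configuration error", {
  expect_error(simulate_series(flat_truth(40, 2), error_model_spec(), 3,
                               seed = 1),
               class = "webaudiometry_config_error")
})

test_that("between-series difference SDs obey variance additivity", {
  # study conditions scaled to 2000 ears; quantization and floor disabled
  spec <- error_model_spec(quantization_step = 0, floor_dbrphl = -Inf)
  st <- simulate_study(cohort_spec(n_subjects = 1000,
                                   home_followup_fraction = 1),
                       spec, seed = 11, max_output = Inf)
  d12 <- paired_diffs(st$measurements, 1, 2)
  expect_equal(sd(d12), sqrt(4.25^2 + 6.64^2), tolerance = 0.05)

  # at 1 kHz the home series adds only the calibration error
  d13 <- paired_diffs(st$measurements, 1, 3, frequency = 1000)
  expect_equal(sd(d13), sqrt(4.25^2 + 6.64^2 + 3.65^2 + 5.00^2),
               tolerance = 0.07)

  # at 250 Hz the nonlinearity component adds on top
  d13_250 <- paired_diffs(st$measurements, 1, 3, frequency = 250)
  expect_equal(sd(d13_250),
               sqrt(4.25^2 + 6.64^2 + 3.65^2 + 5.00^2 + 7.28^2),
               tolerance = 0.07)
})

test_that("the home follow-up subset restricts series 3", {
  st <- simulate_study(seed = 2)
  expect_length(st$followup_subjects, 37)
  s3_subjects <- unique(st$measurements$subject_id[st$measurements$series == 3])
  expect_setequal(s3_subjects, st$followup_subjects)
  expect_length(unique(st$measurements$subject_id[st$measurements$series == 1]),
                51)
})
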