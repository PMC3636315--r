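test_that("variance subtraction is exact, clamped and validated", {
  expect_equal(var_subtract(5, c(3, 4)), list(sd = 0, clamped = FALSE))
  # negative radicand clamps and flags: the 8 kHz nonlinearity case
  res <- var_subtract(10.05, c(8.88, 6.19))
  expect_equal(res$sd, 0)
  expect_true(res$clamped)
  expect_equal(var_subtract(7.88, 4.25)$sd, 6.6356, tolerance = 1e-4)
  expect_error(var_subtract(-1, 2), class = "webaudiometry_domain_error")

  # exact inverse of root-sum-square composition when not clamped
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0, 10); b <- runif(1, 0, 10)
    expect_equal(var_subtract(sqrt(a^2 + b^2), b)$sd, a, tolerance = 1e-12)
  }
})

test_that("single-measurement SD divides the test-retest SD by sqrt(2)", {
  expect_equal(single_measurement_sd(6), 6 / sqrt(2))
  expect_equal(single_measurement_sd(0), 0)
  expect_equal(single_measurement_sd(sqrt(2)), 1)
  expect_error(single_measurement_sd(-2),
               class = "webaudiometry_domain_error")
})

test_that("literature test-retest table is adopted at 6 dB", {
  tab <- reference_testretest_table()
  res <- adopt_testretest_sd(tab)
  expect_equal(res$adopted, 6)
  expect_equal(round(unname(res$per_frequency), 1),
               c(7.1, 5.7, 5.5, 4.8, 5.7, 7.0))
  # constant table adopts the constant
  const <- tab
  const[paste0("f", c(250, 500, 1000, 2000, 4000, 8000))] <- 4
  expect_equal(adopt_testretest_sd(const)$adopted, 4)
  expect_error(adopt_testretest_sd(tab[0, ]),
               class = "webaudiometry_data_error")
})

test_that("series, calibration, population and task SDs chain correctly", {
  expect_equal(series_error_sd(7.88, 4.25)$sd, 6.64, tolerance = 0.005)
  expect_equal(series_error_sd(10.66, 4.25)$sd, 9.78, tolerance = 0.005)
  expect_equal(series_error_sd(4.25, 4.25)$sd, 0)

  expect_equal(calibration_sd(9.28, 6.91)$sd, 6.19, tolerance = 0.005)
  expect_equal(calibration_sd(5, 5)$sd, 0)
  expect_equal(calibration_sd(13, 12)$sd, 5)

  expect_equal(population_sd(5.6, 4.25)$sd, 3.65, tolerance = 0.005)
  expect_equal(population_sd(7, 0)$sd, 7)
  expect_equal(population_sd(4.25, 4.25)$sd, 0)

  expect_equal(calibration_task_sd(6.19, 3.65)$sd, 5.00, tolerance = 0.01)
  expect_equal(calibration_task_sd(5, 3)$sd, 4)
  res <- calibration_task_sd(3, 5)
  expect_equal(res$sd, 0)
  expect_true(res$clamped)
})

test_that("nonlinearity SDs reproduce the published per-frequency values", {
  tbl <- reference_diff_table()
  sigma_cal <- calibration_sd(9.28, 6.91)$sd  # carried unrounded
  nl <- nonlinearity_sds(tbl, sigma_cal)
  expect_equal(nl$per_frequency[["250"]], 7.28, tolerance = 0.01)
  expect_equal(nl$per_frequency[["1000"]], 0)
  expect_equal(nl$per_frequency[["8000"]], 0)
  expect_true(nl$clamped[["8000"]])
  expect_false(nl$clamped[["250"]])
  expect_equal(nl$mean, 4.05, tolerance = 0.01)
})

test_that("the full decomposition reproduces the published budget", {
  b <- reference_budget()
  expect_equal(b$sigma_testretest, 6)
  expect_equal(b$sigma_clin, 4.25, tolerance = 0.01)
  expect_equal(b$sigma_proc, 6.64, tolerance = 0.01)
  expect_equal(b$sigma_series3, 9.78, tolerance = 0.01)
  expect_equal(b$sigma_cal, 6.19, tolerance = 0.01)
  expect_equal(b$sigma_nonlin[["250"]], 7.28, tolerance = 0.01)
  expect_equal(b$sigma_nonlin_mean, 4.05, tolerance = 0.01)
  expect_equal(b$sigma_pop, 3.65, tolerance = 0.01)
  expect_equal(b$sigma_proc_cal, 5.00, tolerance = 0.01)
  expect_equal(b$sigma_gain, 0)
  expect_equal(b$sigma_noise, 0)
  # clamp flags propagate into the budget and report
  expect_true(b$clamped[["sigma_nonlin_8000"]])
  df <- budget_as_data_frame(b)
  expect_true(df$clamped[df$component == "sigma_nonlin_8000"])
  expect_false(df$clamped[df$component == "sigma_nonlin_250"])
})

test_that("a zero-error difference table decomposes to a zero budget", {
  tbl <- difference_sd_table(
    pairing = rep(c("1v2", "1v3"), each = 7),
    stratum = rep(c(as.character(default_grid()), "total"), 2),
    sigma = rep(0, 14))
  b <- decompose(tbl, sigma_testretest = 0, sigma_pop_asc = 0)
  expect_equal(b$sigma_clin, 0)
  expect_equal(b$sigma_proc, 0)
  expect_equal(b$sigma_cal, 0)
  expect_equal(unname(b$sigma_nonlin), rep(0, 6))
  expect_equal(b$sigma_pop, 0)
  expect_equal(b$sigma_proc_cal, 0)
})

test_that("decomposition recovers injected components from simulation", {
  # one full round trip at reduced scale: simulate, summarize, decompose
  spec <- error_model_spec(sigma_clin = 4, sigma_proc = 6,
                           sigma_cal_task = 4, sigma_pop = 3,
                           sigma_nonlin = c("250" = 7, "500" = 3,
                                            "1000" = 0, "2000" = 3,
                                            "4000" = 3, "8000" = 2),
                           quantization_step = 0, floor_dbrphl = -Inf)
  st <- simulate_study(cohort_spec(n_subjects = 2000,
                                   home_followup_fraction = 1),
                       spec, seed = 8, max_output = Inf)
  res <- run_analyze(st$measurements)
  b <- run_decompose(res$agreement, sigma_testretest = 4 * sqrt(2),
                     sigma_pop_asc = 5)  # sqrt(pop^2 + clin^2)
  expect_equal(b$sigma_proc, 6, tolerance = 0.1)
  expect_equal(b$sigma_cal, 5, tolerance = 0.15)  # sqrt(3^2 + 4^2)
  expect_equal(b$sigma_nonlin[["250"]], 7, tolerance = 0.12)
  expect_equal(b$sigma_pop, 3, tolerance = 0.2)
})
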