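# Shared helpers for building small study conditions in tests.

# error model with every stochastic component switched off
zero_noise_spec <- function(...) {
  error_model_spec(sigma_clin = 0, sigma_proc = 0, sigma_cal_task = 0,
                   sigma_pop = 0,
                   sigma_nonlin = c("250" = 0, "500" = 0, "1000" = 0,
                                    "2000" = 0, "4000" = 0, "8000" = 0),
                   sigma_gain = 0, ...)
}

# flat latent audiogram cohort at a fixed level
flat_truth <- function(level, n_ears = 1, grid = default_grid()) {
  do.call(rbind, lapply(seq_len(n_ears), function(i)
    data.frame(subject_id = ceiling(i / 2),
               ear = if (i %% 2) "left" else "right",
               stratum = 1L, frequency_hz = grid, true_db = level)))
}

# paired differences between two series of one measurement frame
paired_diffs <- function(m, a = 1, b = 2, frequency = NULL) {
  key <- function(d) paste(d$subject_id, d$ear, d$frequency_hz)
  da <- m[m$series == a, ]; db <- m[m$series == b, ]
  d <- db$level_db[match(key(da), key(db))] - da$level_db
  if (!is.null(frequency)) d <- d[da$frequency_hz == frequency]
  d[!is.na(d)]
}

# independent numeric minimizer of the Deming objective: profile the
# intercept (ordinary least squares given the slope), then 1-D search on
# the slope of the delta-weighted sum of squared distances
deming_oracle <- function(x, y, delta) {
  f <- function(a) {
    b <- mean(y) - a * mean(x)
    sum((y - a * x - b)^2 / (a^2 + delta))
  }
  a <- stats::optimize(f, c(-20, 20), tol = 1e-10)$minimum
  # Newton polish on the 1-D profile for full precision
  for (i in 1:30) {
    h <- 1e-6 * (abs(a) + 1)
    g <- (f(a + h) - f(a - h)) / (2 * h)
    hess <- (f(a + h) - 2 * f(a) + f(a - h)) / h^2
    if (!is.finite(g) || !is.finite(hess) || hess <= 0) break
    step <- g / hess
    a <- a - step
    if (abs(step) < 1e-12) break
  }
  list(slope = a, intercept = mean(y) - a * mean(x))
}

# deterministic step listener
step_listener <- function(threshold) listener(threshold, slope = 0,
                                              lapse = 0, guess = 0)
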