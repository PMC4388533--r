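test_that("rate schedules validate their grid and interpolate log-linearly", {
  expect_error(rate_schedule(c(0, 10, 10), c(1, 1, 1)), "strictly increasing")
  expect_error(rate_schedule(c(0, 10), c(0.1, -0.1)), "negative rate")
  expect_error(rate_schedule(c(0, 10), c(0.1, NA)), "missing or non-finite")

  s <- rate_schedule(c(0, 10, 20), c(0.01, 0.04, 0.04))
  # log-linear interpolation: geometric midpoint
  expect_equal(rate_at(s, 5), sqrt(0.01 * 0.04))
  expect_equal(rate_at(s, c(0, 10, 20)), c(0.01, 0.04, 0.04))
  expect_error(rate_at(s, 21), "outside the schedule")
  expect_error(rate_at(s, -1), "outside the schedule")

  # zero-valued segments fall back to linear interpolation and stay finite
  z <- rate_schedule(c(0, 10, 20), c(0, 0.02, 0.04))
  expect_equal(rate_at(z, 5), 0.01)
  expect_equal(rate_at(z, 0), 0)

  # continuity across an interior knot
  eps <- 1e-9
  expect_equal(rate_at(s, 10 - eps), rate_at(s, 10 + eps), tolerance = 1e-6)
})

test_that("mortality decomposition matches the mixture identity and trivial cases", {
  ages <- seq(0, 100, by = 1)

  # R = 1 forces m0 = m1 = m regardless of prevalence
  d <- decompose_mortality(constant_course(0.02), constant_course(1),
                           rep(0.3, length(ages)), ages)
  expect_equal(d$m0$rate, rep(0.02, length(ages)))
  expect_equal(d$m1$rate, rep(0.02, length(ages)))

  # p = 0: nobody diseased, m0 = m
  d <- decompose_mortality(constant_course(0.02), constant_course(4),
                           rep(0, length(ages)), ages)
  expect_equal(d$m0$rate, rep(0.02, length(ages)))

  # direct substitution: m = 0.02, p = 0.5, R = 3 -> m0 = 0.01, m1 = 0.03
  d <- decompose_mortality(constant_course(0.02), constant_course(3),
                           rep(0.5, length(ages)), ages)
  expect_equal(d$m0$rate, rep(0.01, length(ages)))
  expect_equal(d$m1$rate, rep(0.03, length(ages)))

  # mixture identity m = p m1 + (1 - p) m0 for age-varying everything
  m <- gompertz_makeham(1e-3, 2e-5, 0.09)
  R <- log_line(1.5, -0.01)
  p <- pmin(0.6, 0.005 * ages)
  d <- decompose_mortality(m, R, p, ages)
  expect_equal(p * d$m1$rate + (1 - p) * d$m0$rate, rate_at(m, ages),
               tolerance = 1e-12)

  expect_error(
    decompose_mortality(constant_course(0.02), constant_course(0.01),
                        rep(0.999999, length(ages)), ages),
    NA)  # denominator stays positive for R in (0, 1]
  expect_error(
    decompose_mortality(constant_course(0.02), rep(-0.5, length(ages)),
                        rep(0.8, length(ages)), ages),
    "degenerate")
})

test_that("relative mortality back-calculation inverts the decomposition", {
  expect_equal(relative_mortality_from_inputs(0.02, 0.3, 0.02), 1)
  expect_equal(relative_mortality_from_inputs(0.03, 0, 0.01), 3)
  expect_equal(relative_mortality_from_inputs(0.03, 0.5, 0.02), 3)
  expect_error(relative_mortality_from_inputs(0.05, 0.5, 0.02),
               "inconsistent")
  expect_error(relative_mortality_from_inputs(0.05, 1, 0.2), "\\[0, 1\\)")

  # round trip: decompose then back-calculate recovers R to 1e-10
  ages <- seq(0, 100, by = 2)
  set.seed(11)
  for (rep in 1:5) {
    m <- runif(1, 0.005, 0.05)
    R <- runif(1, 1.1, 5)
    p <- runif(length(ages), 0, 0.6)
    d <- decompose_mortality(constant_course(m), constant_course(R), p, ages)
    R_back <- relative_mortality_from_inputs(d$m1$rate, p, m)
    expect_equal(R_back, rep(R, length(ages)), tolerance = 1e-10)
  }
})

test_that("proportional-hazards offset fits recover planted factors", {
  ref_i <- log_parabola(-10, 0.15, -0.001)
  ref_R <- log_line(1.6, -0.015)

  # exact multiple at two ages
  f <- fit_log_parabola_offset(ref_i, c(60, 70), 2.5 * rate_at(ref_i, c(60, 70)))
  expect_equal(f$beta, 2.5)
  expect_equal(rate_at(f$shape, c(50, 65, 90)),
               2.5 * rate_at(ref_i, c(50, 65, 90)))

  # single observation on the reference curve
  f <- fit_log_parabola_offset(ref_i, 65, rate_at(ref_i, 65))
  expect_equal(f$beta, 1)

  # ratios 2 and 8 -> geometric mean 4; cross-check by brute-force grid
  # search of the sum of squared log-residuals over the offset
  obs <- c(2, 8) * rate_at(ref_i, c(60, 70))
  f <- fit_log_parabola_offset(ref_i, c(60, 70), obs)
  grid <- seq(log(1.5), log(10), length.out = 20001)
  sse <- vapply(grid, function(b) {
    sum((log(obs) - (b + log(rate_at(ref_i, c(60, 70)))))^2)
  }, numeric(1))
  expect_equal(f$beta, 4, tolerance = 1e-12)
  expect_equal(exp(grid[which.min(sse)]), f$beta, tolerance = 1e-3)

  # log-line analogue, slope preserved
  g <- fit_log_line_offset(ref_R, c(60, 70), 1.5 * rate_at(ref_R, c(60, 70)))
  expect_equal(g$gamma, 1.5)
  expect_equal(g$shape$d1, ref_R$d1)
  g <- fit_log_line_offset(ref_R, 60, rate_at(ref_R, 60))
  expect_equal(g$gamma, 1)
  g <- fit_log_line_offset(ref_R, c(60, 70), c(2, 8) * rate_at(ref_R, c(60, 70)))
  expect_equal(g$gamma, 4, tolerance = 1e-12)

  expect_error(fit_log_parabola_offset(ref_i, numeric(0), numeric(0)),
               "at least one")
  expect_error(fit_log_parabola_offset(ref_i, 60, -0.1), "positive")
})

test_that("offset fit recovers a planted factor with vanishing bias as noise shrinks", {
  ref_i <- log_parabola(-10, 0.15, -0.001)
  beta <- 1.4
  ages <- c(60, 70)
  set.seed(21)
  bias <- vapply(c(0.1, 0.01, 0.001), function(sd) {
    lb <- replicate(300, {
      obs <- beta * rate_at(ref_i, ages) * exp(rnorm(2, 0, sd))
      log(fit_log_parabola_offset(ref_i, ages, obs)$beta)
    })
    mean(lb) - log(beta)
  }, numeric(1))
  # unbiased estimator of the log-offset: bias bounded by 3 MC standard
  # errors (SE = sd / sqrt(2 * 300)) at every noise level
  expect_true(all(abs(bias) < 3 * c(0.1, 0.01, 0.001) / sqrt(600)))
  expect_true(abs(bias[3]) < abs(bias[1]) + 1e-6)
})

test_that("intervention scaling and onset cutoff behave and commute", {
  i <- log_parabola(-10, 0.15, -0.001)
  ages <- c(30, 35, 40, 60, 90)

  expect_equal(rate_at(apply_intervention(i, 0), ages), rate_at(i, ages))
  expect_equal(rate_at(apply_intervention(i, 0.19), ages),
               0.81 * rate_at(i, ages))
  expect_equal(rate_at(apply_intervention(constant_course(0.01), 0.5), ages),
               rep(0.005, 5))
  expect_error(apply_intervention(i, 1), "\\[0, 1\\)")
  expect_error(apply_intervention(i, -0.1), "\\[0, 1\\)")

  cut <- enforce_onset_cutoff(constant_course(0.01), 35)
  expect_equal(rate_at(cut, c(30, 35, 40)), c(0, 0, 0.01))
  # right-continuous evaluation used by the integrals
  expect_equal(rate_at(cut, c(30, 35, 40), lower_open = TRUE),
               c(0, 0.01, 0.01))

  # order independence
  a <- apply_intervention(enforce_onset_cutoff(i, 35), 0.19)
  b <- enforce_onset_cutoff(apply_intervention(i, 0.19), 35)
  expect_equal(rate_at(a, ages), rate_at(b, ages))

  # onset 0 leaves positive ages untouched
  c0 <- enforce_onset_cutoff(constant_course(0.01), 0)
  expect_equal(rate_at(c0, c(1, 50)), c(0.01, 0.01))
})
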