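test_that("survival path matches closed forms and its invariants", {
  ages <- seq(0, 110, by = 0.1)
  S0 <- survival_path(constant_course(0), ages)
  expect_equal(S0$surv, rep(1, length(ages)))

  S <- survival_path(constant_course(0.02), ages)
  expect_equal(curve_at(S, 50), exp(-1), tolerance = 1e-12)
  expect_equal(S$surv[1L], 1)
  expect_true(all(diff(S$surv) <= 0))
  expect_true(all(S$surv > 0 & S$surv <= 1))

  # piecewise-constant mortality: product of segment exponentials; the
  # trapezoid quadrature is exact when knots lie on the grid
  m <- rate_schedule(c(0, 50, 110), c(0.01, 0.01, 0.04))
  Sp <- survival_path(m, ages)
  seg <- function(a) {
    exp(-0.01 * pmin(a, 50)) *
      ifelse(a > 50, exp(-integrate(function(u) rate_at(m, u), 50, a,
                                    rel.tol = 1e-12)$value), 1)
  }
  expect_equal(curve_at(Sp, 80), seg(80), tolerance = 1e-6)
})

test_that("lifetime risk matches competing-exponential closed forms", {
  ages <- seq(0, 110, by = 0.05)

  expect_equal(lifetime_risk(constant_course(0), constant_course(0.02), ages)$risk,
               rep(0, length(ages)))

  # no mortality: P(a) = 1 - exp(-i a)
  P <- lifetime_risk(constant_course(0.01), constant_course(0), ages)
  expect_equal(curve_at(P, c(10, 50, 100)), 1 - exp(-0.01 * c(10, 50, 100)),
               tolerance = 1e-6)

  # competing exponential: P(a) = i/(i+m0) (1 - exp(-(i+m0) a)) -> 1/3
  P <- lifetime_risk(constant_course(0.01), constant_course(0.02), ages)
  cf <- function(a) 0.01 / 0.03 * (1 - exp(-0.03 * a))
  expect_equal(curve_at(P, c(10, 50, 100)), cf(c(10, 50, 100)),
               tolerance = 1e-6)
  expect_lt(abs(P$risk[length(ages)] - 1 / 3), 0.02)
  expect_true(all(diff(P$risk) >= 0))
  expect_true(all(P$risk <= 1))
})

test_that("absolute risk reduction is a pointwise difference with grid checks", {
  ages <- seq(0, 110, by = 0.1)
  P <- lifetime_risk(constant_course(0.01), constant_course(0.02), ages)
  expect_equal(absolute_risk_reduction(P, P)$risk, rep(0, length(ages)))
  P2 <- lifetime_risk(constant_course(0.008), constant_course(0.02), ages)
  arr <- absolute_risk_reduction(P, P2)
  expect_true(all(arr$risk >= 0))
  Pshort <- lifetime_risk(constant_course(0.01), constant_course(0.02),
                          seq(0, 100, by = 0.1))
  expect_error(absolute_risk_reduction(P, Pshort), "same age grid")
})

test_that("case counts match the first-event closed form and bound by lifetime risk", {
  ages <- seq(0, 110, by = 0.05)
  S <- survival_path(constant_course(0.02), ages)
  expect_equal(case_count(constant_course(0), rep(0, length(ages)), S, 1e5), 0)

  # with R = 1 (m0 = m1 = m) the healthy survivors are exp(-(i+m) a), so
  # C/N0 is the competing-risk first-event probability
  inp <- const_inputs(0.01, 0.02, 1)
  p <- solve_cohort_prevalence(inp, grid_step = 0.05, check = FALSE)
  C <- case_count(constant_course(0.01), p, S, 1e5)
  cf <- 0.01 / 0.03 * (1 - exp(-0.03 * 110))
  expect_equal(C / 1e5, cf, tolerance = 1e-5)

  # consistency bound: C/N0 never exceeds the lifetime risk at a_max
  P <- lifetime_risk(constant_course(0.01), constant_course(0.02), ages)
  expect_lte(C / 1e5, P$risk[length(ages)] + 1e-10)
})

test_that("prevented cases via the single integral equal the case-count difference", {
  study <- clean_study()
  os <- suppressWarnings(
    scenario_contrast(
      bau = scenario_inputs(log_parabola(-10, 0.15, -0.001),
                            gompertz_makeham(5e-4, 2.5e-5, 0.092),
                            log_line(1.9, -0.02), scenario = "BAU"),
      iat = scenario_inputs(apply_intervention(log_parabola(-10, 0.15, -0.001), 0.19),
                            gompertz_makeham(5e-4, 2.5e-5, 0.092),
                            log_line(1.9, -0.02), scenario = "IAT")))
  expect_equal(os$delta_cases, os$cases_bau - os$cases_iat,
               tolerance = 1e-8 * os$cases_bau)
  expect_gt(os$prevented_fraction, 0)
  expect_lt(os$prevented_fraction, 1)
})

test_that("Sullivan disease-free life expectancy matches exponential closed forms", {
  # long horizon so the truncated upper limit is numerically exact
  ages <- seq(0, 1000, by = 0.1)
  S <- survival_path(constant_course(0.02), ages)
  n <- length(ages)

  expect_equal(disease_free_life_expectancy(rep(0, n), S, 35), 50,
               tolerance = 1e-6)
  expect_equal(disease_free_life_expectancy(rep(0, n), S, 70), 50,
               tolerance = 1e-6)
  expect_equal(disease_free_life_expectancy(as.numeric(ages >= 35), S, 35), 0,
               tolerance = 1e-9)
  expect_equal(disease_free_life_expectancy(rep(0.5, n), S, 35), 25,
               tolerance = 1e-5)
  expect_error(disease_free_life_expectancy(rep(0, n), S, 1000), "inside")
})

test_that("all scenario contrasts vanish identically at h = 0", {
  inc <- log_parabola(-10.6, 0.16, -0.001)
  gm <- gompertz_makeham(5e-4, 2.5e-5, 0.092)
  rel <- log_line(1.9, -0.02)
  bau <- scenario_inputs(inc, gm, rel, scenario = "BAU")
  iat <- scenario_inputs(apply_intervention(inc, 0), gm, rel, scenario = "IAT")
  os <- suppressWarnings(scenario_contrast(bau, iat))
  expect_identical(os$arr$risk, rep(0, length(os$arr$age)))
  expect_identical(os$delta_cases, 0)
  expect_identical(os$delta_disease_free, 0)
})

test_that("outcome integrals are stable under grid halving", {
  inc <- enforce_onset_cutoff(log_parabola(-10.6, 0.16, -0.001), 35)
  gm <- gompertz_makeham(5e-4, 2.5e-5, 0.092)
  rel <- log_line(1.9, -0.02)
  bau <- scenario_inputs(inc, gm, rel, scenario = "BAU")
  iat <- scenario_inputs(apply_intervention(inc, 0.19), gm, rel, scenario = "IAT")
  o1 <- suppressWarnings(scenario_contrast(bau, iat, grid_step = 0.05))
  o2 <- suppressWarnings(scenario_contrast(bau, iat, grid_step = 0.025))
  rel_change <- function(a, b) abs(a - b) / pmax(abs(a), 1e-12)
  expect_lt(rel_change(o1$cases_bau, o2$cases_bau), 1e-6)
  expect_lt(rel_change(o1$prevented_fraction, o2$prevented_fraction), 1e-6)
  expect_lt(rel_change(o1$ef_bau, o2$ef_bau), 1e-6)
  expect_lt(max(rel_change(curve_at(o1$risk_bau, c(60, 90)),
                           curve_at(o2$risk_bau, c(60, 90)))), 1e-6)
})
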