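test_that("synthetic config validates its epidemiological invariants", {
  expect_error(synthetic_config(incidence_coef = c(-10, 0.1, 0.001)),
               "must be negative")
  expect_error(synthetic_config(relmort_coef = c(1.5, 0.01)), "must be negative")
  expect_error(synthetic_config(incidence_coef = c(-10, 0.3, -0.005)),
               "peak age")  # peak at 30, implausibly early
  expect_error(synthetic_config(beta = 0), "positive")
})

test_that("reference shapes are positive, unimodal in log scale, and sex-shifted", {
  cfg <- synthetic_config()
  m <- generate_reference_shapes(cfg, "male")
  f <- generate_reference_shapes(cfg, "female")
  ages <- seq(35, 110, by = 0.5)
  im <- rate_at(m$incidence, ages)
  expect_true(all(is.finite(im) & im > 0))
  # log-parabola with c2 < 0: increments of log-incidence strictly decrease
  expect_true(all(diff(diff(log(im))) < 0))
  peak <- ages[which.max(im)]
  expect_gt(peak, 40); expect_lt(peak, 100)
  # female level offset only: constant log-ratio
  expect_equal(log(rate_at(f$incidence, ages)) - log(im),
               rep(cfg$female_c0_offset, length(ages)))

  # direct evaluation of the log-line
  r <- log_line(log(3), -0.02)
  expect_equal(rate_at(r, 0), 3)
  expect_equal(rate_at(r, 55), 3 * exp(-1.1))
})

test_that("Gompertz-Makeham mortality evaluates exactly and kills the cohort by 110", {
  m <- generate_general_mortality(0.001, 2e-5, 0.095)
  expect_equal(rate_at(m, 70), 0.001 + 2e-5 * exp(0.095 * 70), tolerance = 1e-9)
  m0 <- generate_general_mortality(0.002, 2e-5, 0)
  expect_equal(rate_at(m0, c(10, 80)), rep(0.00202, 2))
  expect_error(generate_general_mortality(-0.001, 2e-5, 0.1), "non-negative")
  expect_error(generate_general_mortality(0.001, 0, 0.1), "positive")

  # default-parameter survival to 110 is negligible, for both sexes
  cfg <- synthetic_config()
  for (gm in list(cfg$gm_male, cfg$gm_female)) {
    sched <- generate_general_mortality(gm[1], gm[2], gm[3])
    S <- survival_path(sched, seq(0, 110, by = 0.1))
    expect_lt(S$surv[length(S$surv)], 1e-4)
  }

  # life expectancy from the tabulated schedule matches an independent
  # quadrature of the analytic hazard
  gm <- cfg$gm_male
  H <- function(a) {
    vapply(a, function(x) integrate(function(u) gm[1] + gm[2] * exp(gm[3] * u),
                                    0, x, rel.tol = 1e-10)$value, numeric(1))
  }
  le_exact <- integrate(function(a) exp(-H(a)), 0, 110, rel.tol = 1e-8)$value
  sched <- generate_general_mortality(gm[1], gm[2], gm[3])
  S <- survival_path(sched, seq(0, 110, by = 0.1))
  le_grid <- sum(diff(S$age) * (S$surv[-1] + S$surv[-length(S$surv)]) / 2)
  expect_equal(le_grid, le_exact, tolerance = 1e-4)
})

test_that("anchor observations are consistent multiples of the reference and seeded", {
  cfg <- synthetic_config()
  clean <- generate_anchor_observations(cfg, "male", noise_sd = 0)
  ref <- generate_reference_shapes(cfg, "male")

  # noise-free: incidence is exactly beta x reference, and the relative
  # mortality back-formula recovers gamma x reference
  expect_equal(clean$i, cfg$beta * rate_at(ref$incidence, clean$age))
  R_back <- relative_mortality_from_inputs(clean$m1, clean$p, clean$m)
  expect_equal(R_back, cfg$gamma * rate_at(ref$relative_mortality, clean$age),
               tolerance = 1e-10)

  o1 <- generate_anchor_observations(cfg, "male", noise_sd = 0.1, seed = 4)
  o2 <- generate_anchor_observations(cfg, "male", noise_sd = 0.1, seed = 4)
  o3 <- generate_anchor_observations(cfg, "male", noise_sd = 0.1, seed = 5)
  expect_identical(o1$i, o2$i)
  expect_false(any(o1$i == o3$i))

  # planted-offset recovery within sampling tolerance of the mean log-ratio
  set.seed(31)
  sd <- 0.05
  lb <- replicate(200, {
    o <- generate_anchor_observations(cfg, "male", noise_sd = sd)
    log(fit_log_parabola_offset(ref$incidence, o$age, o$i)$beta)
  })
  expect_lt(abs(mean(lb) - log(cfg$beta)), 3 * sd / sqrt(2 * 200))
})

test_that("noise-free study round-trips through fit, solve and outcomes exactly", {
  study <- clean_study()
  cfg <- study$config
  for (s in c("male", "female")) {
    anchors <- study$sexes[[s]]$anchors
    ref <- study$sexes[[s]]$reference
    fit_i <- fit_log_parabola_offset(ref$incidence, anchors$age, anchors$i)
    R_obs <- relative_mortality_from_inputs(anchors$m1, anchors$p, anchors$m)
    fit_R <- fit_log_line_offset(ref$relative_mortality, anchors$age, R_obs)
    expect_equal(fit_i$beta, cfg$beta, tolerance = 1e-9)
    expect_equal(fit_R$gamma, cfg$gamma, tolerance = 1e-9)
  }
})

test_that("prevented fraction grows with the planted effect size", {
  study <- clean_study()
  pf <- vapply(c(0.1, 0.19, 0.3), function(h) {
    os <- suppressWarnings(illnessdeath:::contrast_from_anchors(
      study, "male", study$sexes$male$anchors, h,
      report_ages = 80, grid_step = 0.1, a_max = 110))
    os$prevented_fraction
  }, numeric(1))
  expect_true(all(pf > 0 & pf < 1))
  expect_true(all(diff(pf) > 0))
})
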