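#' Configuration of the synthetic study inputs
#'
#' Describes a fully synthetic but epidemiologically structured input set for
#' the projection pipeline: a log-parabolic reference incidence and a
#' log-linear reference relative mortality (the "reference population"
#' shapes used for proportional-hazards extrapolation), Gompertz-Makeham
#' general mortality per sex, planted calibration factors `beta` (incidence)
#' and `gamma` (relative mortality) linking the target population to the
#' reference, anchor ages at which the target population is observed, and
#' the intervention's relative-risk-reduction distribution. The defaults are
#' chosen to resemble adult-onset type 2 diabetes in a European population:
#' incidence peaking between ages 75 and 85 at roughly 1.5% per year,
#' relative mortality declining from about 4 at age 35 to below 2 at high
#' ages, and general mortality giving life expectancies near 77 (men) and 82
#' (women) years with survival to age 110 below 1e-4. They are synthetic
#' values, not estimates from any cohort.
#'
#' @param incidence_coef reference log-parabola coefficients `c(c0, c1, c2)`
#'   (male); `c2` must be negative so log-incidence is unimodal.
#' @param relmort_coef reference log-line coefficients `c(d0, d1)` (male);
#'   `d1` must be negative (relative mortality declines with age).
#' @param female_c0_offset,female_d0_offset additive log-scale offsets
#'   applied to the female reference shapes (sex differences enter through
#'   the level only).
#' @param gm_male,gm_female Gompertz-Makeham parameters
#'   `c(lambda, phi, theta)` per sex, see [gompertz_makeham()].
#' @param beta,gamma planted proportional-hazards factors (target =
#'   factor x reference), both `> 0`.
#' @param anchor_ages ages at which anchor observations are taken
#'   (default 60 and 70).
#' @param anchor_log_sd log-scale SD of the sampling noise on anchor
#'   observations (default 0.1).
#' @param h_mean,h_ci mean and 95% CI of the intervention's relative risk
#'   reduction; defaults 0.19 and (0.11, 0.27).
#' @param onset_age,birth_year,cohort_size cohort metadata, see
#'   [scenario_inputs()].
#' @param a_max,grid_step numerical grid defaults for the pipeline.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(incidence_coef = c(-10.6, 0.16, -0.001),
                             relmort_coef = c(1.8931, -0.02),
                             female_c0_offset = -0.45,
                             female_d0_offset = 0.15,
                             gm_male = c(5e-4, 3e-5, 0.095),
                             gm_female = c(4e-4, 9e-6, 0.106),
                             beta = 1.25, gamma = 0.9,
                             anchor_ages = c(60, 70),
                             anchor_log_sd = 0.1,
                             h_mean = 0.19, h_ci = c(0.11, 0.27),
                             onset_age = 35, birth_year = 1985,
                             cohort_size = 1e5,
                             a_max = 110, grid_step = 0.05) {
  if (incidence_coef[3L] >= 0) stop("'incidence_coef[3]' (c2) must be negative")
  if (relmort_coef[2L] >= 0) stop("'relmort_coef[2]' (d1) must be negative")
  if (beta <= 0 || gamma <= 0) stop("'beta' and 'gamma' must be positive")
  if (anchor_log_sd < 0) stop("'anchor_log_sd' must be non-negative")
  peak <- -incidence_coef[2L] / (2 * incidence_coef[3L])
  if (peak <= 40 || peak >= 100) {
    stop(sprintf("incidence peak age %.1f outside the plausible range (40, 100)", peak))
  }
  cfg <- list(incidence_coef = incidence_coef, relmort_coef = relmort_coef,
              female_c0_offset = female_c0_offset,
              female_d0_offset = female_d0_offset,
              gm_male = gm_male, gm_female = gm_female,
              beta = beta, gamma = gamma,
              anchor_ages = anchor_ages, anchor_log_sd = anchor_log_sd,
              h_mean = h_mean, h_ci = h_ci,
              onset_age = onset_age, birth_year = birth_year,
              cohort_size = cohort_size, a_max = a_max, grid_step = grid_step)
  class(cfg) <- "synthetic_config"
  # constructor for side-effect validation of the mortality parameters
  gompertz_makeham(gm_male[1L], gm_male[2L], gm_male[3L])
  gompertz_makeham(gm_female[1L], gm_female[2L], gm_female[3L])
  cfg
}

#' Reference shapes of the synthetic study
#'
#' Returns the reference population's incidence log-parabola and relative
#' mortality log-line for one sex. Sex differences are level shifts in log
#' space.
#'
#' @param config a [synthetic_config()].
#' @param sex `"male"` or `"female"`.
#' @return list with `incidence` ([log_parabola()]) and `relative_mortality`
#'   ([log_line()]).
#' @export
generate_reference_shapes <- function(config, sex = c("male", "female")) {
  stopifnot(inherits(config, "synthetic_config"))
  sex <- match.arg(sex)
  c0 <- config$incidence_coef[1L] +
    if (sex == "female") config$female_c0_offset else 0
  d0 <- config$relmort_coef[1L] +
    if (sex == "female") config$female_d0_offset else 0
  list(incidence = log_parabola(c0, config$incidence_coef[2L],
                                config$incidence_coef[3L]),
       relative_mortality = log_line(d0, config$relmort_coef[2L]))
}

#' Tabulated Gompertz-Makeham general mortality
#'
#' Evaluates the hazard `m(a) = lambda + phi exp(theta a)` on an age grid and
#' returns it as a [rate_schedule()], the tabular form the projection
#' pipeline consumes (standing in for an official population life table).
#'
#' @param lambda,phi,theta see [gompertz_makeham()].
#' @param ages tabulation grid (default half-year steps on `[0, 110]`).
#' @return a [rate_schedule()].
#' @export
generate_general_mortality <- function(lambda, phi, theta,
                                       ages = seq(0, 110, by = 0.5)) {
  gm <- gompertz_makeham(lambda, phi, theta)
  rate_schedule(ages, rate_at(gm, ages))
}

#' Anchor observations of the synthetic target population
#'
#' Emulates what a cohort study reports at a few anchor ages: the incidence
#' `i`, the mortality of the diseased `m1`, the prevalence `p`, alongside
#' the (exactly known) general mortality `m`. The underlying truth is
#' internally consistent: the target incidence and relative mortality are
#' the planted multiples (`beta`, `gamma`) of the reference shapes, the
#' prevalence at the anchor ages is the solved model prevalence under those
#' rates, and `m1` follows from the mortality decomposition — so
#' back-calculating `R` from `(m1, p, m)` recovers `gamma` times the
#' reference exactly when the noise is zero. Observation noise is
#' log-normal, multiplying `i`, `m1` and `p` by `exp(N(0, sd^2))`
#' independently.
#'
#' @param config a [synthetic_config()].
#' @param sex `"male"` or `"female"`.
#' @param noise_sd log-scale SD of the observation noise; default taken from
#'   `config$anchor_log_sd`. Use 0 for noise-free anchors.
#' @param seed optional integer seed for reproducible noise.
#' @return data.frame with columns `age`, `i`, `m1`, `p`, `m` and attributes
#'   `truth` (the noise-free version) and `sex`.
#' @export
generate_anchor_observations <- function(config, sex = c("male", "female"),
                                         noise_sd = config$anchor_log_sd,
                                         seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  sex <- match.arg(sex)
  truth <- anchor_truth(config, sex)
  if (!is.null(seed)) set.seed(seed)
  obs <- truth
  if (noise_sd > 0) {
    n <- nrow(truth)
    obs$i <- truth$i * exp(stats::rnorm(n, 0, noise_sd))
    obs$m1 <- truth$m1 * exp(stats::rnorm(n, 0, noise_sd))
    obs$p <- pmin(truth$p * exp(stats::rnorm(n, 0, noise_sd)), 0.99)
  }
  attr(obs, "truth") <- truth
  attr(obs, "sex") <- sex
  obs
}

# Noise-free anchor quantities implied by the planted shapes: solves the
# business-as-usual prevalence and decomposes mortality at the anchor ages.
anchor_truth <- function(config, sex) {
  shapes <- generate_reference_shapes(config, sex)
  inc <- scale_log_course(shapes$incidence, config$beta)
  rel <- scale_log_course(shapes$relative_mortality, config$gamma)
  gm_par <- if (sex == "male") config$gm_male else config$gm_female
  gm <- generate_general_mortality(gm_par[1L], gm_par[2L], gm_par[3L],
                                   ages = seq(0, config$a_max, by = 0.5))
  inputs <- scenario_inputs(inc, gm, rel, sex = sex, scenario = "BAU",
                            onset_age = config$onset_age,
                            birth_year = config$birth_year,
                            cohort_size = config$cohort_size)
  path <- solve_cohort_prevalence(inputs, config$grid_step, config$a_max,
                                  check = FALSE)
  a <- config$anchor_ages
  p <- curve_at(path, a)
  m <- rate_at(gm, a)
  R <- rate_at(rel, a)
  m0 <- m / (1 + p * (R - 1))
  data.frame(age = a, i = rate_at(inc, a), m1 = R * m0, p = p, m = m)
}

# Multiply a parametric log-scale course by a constant factor.
scale_log_course <- function(shape, factor) {
  if (inherits(shape, "log_parabola")) {
    log_parabola(shape$c0 + log(factor), shape$c1, shape$c2)
  } else if (inherits(shape, "log_line")) {
    log_line(shape$d0 + log(factor), shape$d1)
  } else stop("not a parametric log-scale course")
}

#' Build a complete synthetic study
#'
#' Assembles everything one run of the projection needs, for both sexes: the
#' reference shapes, the tabulated general mortality, and anchor
#' observations of the target population (noisy or noise-free). This is the
#' synthetic stand-in for the real data flow, in which anchor estimates from
#' a cohort study are combined with registry reference shapes and official
#' mortality tables.
#'
#' @param config a [synthetic_config()].
#' @param noise_sd log-scale SD of the anchor observation noise (default
#'   from `config`; 0 gives the exactly consistent noise-free study).
#' @param seed optional seed for the observation noise.
#' @return An object of class `"synthetic_study"`: `config` plus a `sexes`
#'   list with per-sex `reference` shapes, `general_mortality` schedule and
#'   `anchors` data.frame.
#' @export
synthetic_study <- function(config = synthetic_config(),
                            noise_sd = config$anchor_log_sd, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  sexes <- lapply(c(male = "male", female = "female"), function(s) {
    gm_par <- if (s == "male") config$gm_male else config$gm_female
    list(
      reference = generate_reference_shapes(config, s),
      general_mortality = generate_general_mortality(
        gm_par[1L], gm_par[2L], gm_par[3L],
        ages = seq(0, config$a_max, by = 0.5)),
      anchors = generate_anchor_observations(config, s, noise_sd = noise_sd)
    )
  })
  structure(list(config = config, sexes = sexes), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic study:\n")
  for (s in names(x$sexes)) {
    a <- x$sexes[[s]]$anchors
    cat(sprintf("  %s anchors (age: i, m1, p):\n", s))
    for (k in seq_len(nrow(a))) {
      cat(sprintf("    %g: %.5f, %.5f, %.4f\n", a$age[k], a$i[k], a$m1[k], a$p[k]))
    }
  }
  invisible(x)
}
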