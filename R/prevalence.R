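#' Solve the cohort-line prevalence equation
#'
#' In the illness-death model (healthy, diseased, dead) the age- and
#' time-specific prevalence `p(t, a)` of an irreversible disease satisfies a
#' first-order partial differential equation in period and age. When none of
#' the transition rates carries a calendar-time trend, the equation along the
#' life line of a birth cohort (`t = t0 + a`) reduces to the ordinary
#' differential equation
#' \deqn{dp/da = (1 - p)\,[\,i - m\,p(R - 1)/(1 + p(R - 1))\,],}
#' where `i` is the incidence, `m` the general mortality and `R` the relative
#' mortality of the diseased. The bracketed term is the incidence minus the
#' general mortality times the population attributable fraction. The equation
#' is integrated with a classical fourth-order Runge-Kutta scheme on a fixed
#' age grid starting from `p = 0` at birth (incidence is zero below the onset
#' age, so `p` stays 0 there).
#'
#' @param inputs a [scenario_inputs()] object.
#' @param grid_step age step of the integration grid in years (default 0.05,
#'   at which the downstream trapezoidal outcome integrals are stable to
#'   better than 1e-6 relative under grid halving).
#' @param a_max upper age limit in years (default 110); improper upper limits
#'   in downstream integrals are truncated here.
#' @param check if `TRUE` (default) the solve is repeated at half the step
#'   and the two solutions must agree within `check_tol`; failure is an
#'   error reporting the step size and the worst age.
#' @param check_tol tolerance for the convergence self-check (default 1e-6).
#' @return An object of class `"prevalence_path"`: a list with `age` (the
#'   grid), `prevalence` (proportions in `[0, 1]`), `sex`, `scenario`, and
#'   the solver settings.
#' @examples
#' inp <- scenario_inputs(constant_course(0.01), constant_course(0.01),
#'                        constant_course(2), onset_age = 35)
#' path <- solve_cohort_prevalence(inp)
#' max(path$prevalence)
#' @export
solve_cohort_prevalence <- function(inputs, grid_step = 0.05, a_max = 110,
                                    check = TRUE, check_tol = 1e-6) {
  stopifnot(inherits(inputs, "scenario_inputs"))
  if (!is.finite(grid_step) || grid_step <= 0) stop("'grid_step' must be positive")
  if (a_max <= inputs$onset_age) stop("'a_max' must exceed the onset age")

  p <- rk4_on_grid(inputs, grid_step, a_max)
  ages <- seq(0, a_max, by = grid_step)

  if (check) {
    R_end <- rate_at(inputs$relative_mortality, a_max)
    if (R_end < 1) {
      warning(sprintf(
        "relative mortality falls below 1 before age %g (R(%g) = %.3f); no floor is applied",
        a_max, a_max, R_end))
    }
  }

  if (check) {
    p_half <- rk4_on_grid(inputs, grid_step / 2, a_max)
    p_half <- p_half[seq(1, length(p_half), by = 2L)]
    dev <- abs(p - p_half)
    if (max(dev) > check_tol) {
      stop(sprintf(
        "prevalence solution not converged: step %g vs %g differ by %.3g at age %g",
        grid_step, grid_step / 2, max(dev), ages[which.max(dev)]))
    }
  }

  structure(list(age = ages, prevalence = p,
                 sex = inputs$sex, scenario = inputs$scenario,
                 onset_age = inputs$onset_age,
                 grid_step = grid_step, a_max = a_max),
            class = "prevalence_path")
}

# Evaluate the three rate courses at half-step resolution and run the
# compiled RK4 kernel. The prevalence is identically 0 up to the onset age,
# so integration starts at the onset grid node; the incidence is evaluated
# right-continuously there (lower_open), keeping the integrand smooth on the
# integration range despite the cutoff's jump.
rk4_on_grid <- function(inputs, grid_step, a_max) {
  n <- round(a_max / grid_step)
  if (abs(n * grid_step - a_max) > 1e-9) {
    stop("'a_max' must be an integer multiple of 'grid_step'")
  }
  k0 <- round(inputs$onset_age / grid_step)
  if (abs(k0 * grid_step - inputs$onset_age) > 1e-9) {
    stop("the onset age must fall on the integration grid; adjust 'grid_step'")
  }
  half_ages <- seq(0, a_max, by = grid_step / 2)
  i <- rate_at(inputs$incidence, half_ages, lower_open = TRUE)
  m <- rate_at(inputs$general_mortality, half_ages)
  R <- rate_at(inputs$relative_mortality, half_ages)
  if (any(!is.finite(i)) || any(!is.finite(m)) || any(!is.finite(R))) {
    stop("rates are not finite everywhere on [0, a_max]")
  }
  idx <- (2L * k0 + 1L):length(half_ages)
  c(rep(0, k0), rk4_prevalence_cpp(i[idx], m[idx], R[idx], grid_step, 0))
}

#' @export
print.prevalence_path <- function(x, ...) {
  cat(sprintf(
    "prevalence path (%s, %s): %d grid ages in [0, %g], peak prevalence %.4f at age %g\n",
    x$sex, x$scenario, length(x$age), x$a_max,
    max(x$prevalence), x$age[which.max(x$prevalence)]))
  invisible(x)
}

#' @export
as.data.frame.prevalence_path <- function(x, ...) {
  data.frame(age = x$age, prevalence = x$prevalence,
             sex = x$sex, scenario = x$scenario)
}
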