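#' Cohort survival function from general mortality
#'
#' `S(a) = exp(-integral_0^a m(u) du)`, the probability of a cohort member
#' surviving (in any state) to age `a`. The cumulative hazard is accumulated
#' with the trapezoidal rule on the supplied grid.
#'
#' @param m general mortality: an `age_course` or numeric vector on `ages`.
#' @param ages age grid (years), starting at 0.
#' @return An object of class `"survival_path"` with fields `age` and `surv`.
#' @export
survival_path <- function(m, ages) {
  if (ages[1L] != 0) stop("the survival grid must start at age 0")
  m <- course_values(m, ages)
  S <- exp(-cumtrapz_grid(ages, m))
  structure(list(age = ages, surv = S), class = "survival_path")
}

#' @export
print.survival_path <- function(x, ...) {
  cat(sprintf("survival path on [0, %g]: S(%g) = %.3g\n",
              max(x$age), max(x$age), x$surv[length(x$surv)]))
  invisible(x)
}

#' Lifetime risk of contracting the disease
#'
#' Cumulative risk of disease onset before age `a` in the birth cohort, with
#' death while healthy acting as a competing risk:
#' \deqn{P(a) = \int_0^a i(\tau) \exp\!\Big(-\int_0^\tau i(u) + m_0(u)\,du\Big) d\tau.}
#' Here `m_0` is the mortality of the non-diseased, obtained from the general
#' mortality via `m0 = m / (1 + p (R - 1))` with the scenario's own
#' prevalence path, so `m0` is scenario-specific while `m` is shared.
#' Both integrals are accumulated cumulatively on the grid (trapezoidal
#' rule), so the whole curve costs one pass.
#'
#' When the incidence carries an onset-age cutoff, pass `onset_age` so the
#' incidence integrals start exactly at the onset grid node (right-continuous
#' evaluation); otherwise the jump at the cutoff would cost the quadrature an
#' order of accuracy.
#'
#' @param i incidence: `age_course` or numeric vector on `ages`.
#' @param m0 mortality of the non-diseased: `age_course` or numeric vector.
#' @param ages age grid starting at 0.
#' @param onset_age optional onset age (years) at which disease-related
#'   integrals start; `NULL` for none.
#' @return An object of class `"risk_curve"`: fields `age`, `risk`
#'   (non-decreasing proportions).
#' @export
lifetime_risk <- function(i, m0, ages, onset_age = NULL) {
  if (ages[1L] != 0) stop("the risk integral starts at age 0")
  i <- course_values(i, ages, lower_open = TRUE)
  m0 <- course_values(m0, ages)
  H <- cum_onset(ages, i, onset_age) + cumtrapz_grid(ages, m0)
  P <- cum_onset(ages, i * exp(-H), onset_age)
  structure(list(age = ages, risk = P), class = "risk_curve")
}

# Cumulative trapezoidal integral of an integrand that is identically zero
# below the onset age and jumps there: accumulation restarts at the onset
# grid node so the panel straddling the jump contributes nothing.
cum_onset <- function(ages, y, onset_age = NULL) {
  C <- cumtrapz_grid(ages, y)
  if (is.null(onset_age) || onset_age <= ages[1L]) return(C)
  k0 <- match(TRUE, ages >= onset_age - 1e-9)
  if (is.na(k0)) return(C)
  C <- C - C[k0]
  C[seq_len(k0)] <- 0
  C
}

#' @export
print.risk_curve <- function(x, ...) {
  cat(sprintf("lifetime risk curve: P(%g) = %.4f\n",
              max(x$age), x$risk[length(x$risk)]))
  invisible(x)
}

#' Evaluate a grid curve at arbitrary ages
#'
#' Linear interpolation of a solved path (risk curve, survival path or
#' prevalence path) at ages inside its grid.
#'
#' @param x a `risk_curve`, `survival_path` or `prevalence_path`.
#' @param age ages at which to evaluate.
#' @return numeric vector.
#' @export
curve_at <- function(x, age) {
  v <- if (inherits(x, "risk_curve")) x$risk
       else if (inherits(x, "survival_path")) x$surv
       else if (inherits(x, "prevalence_path")) x$prevalence
       else stop("no curve values found in 'x'")
  if (any(age < min(x$age)) || any(age > max(x$age))) {
    stop("evaluation age outside the curve's grid range")
  }
  stats::approx(x$age, v, xout = age)$y
}

#' Absolute risk reduction between two scenarios
#'
#' Pointwise difference of the lifetime-risk curves,
#' `ARR(a) = P_BAU(a) - P_IAT(a)`; non-negative at every age whenever the
#' intervention does not increase incidence.
#'
#' @param risk_bau,risk_iat [lifetime_risk()] curves on the same age grid.
#' @return A `risk_curve` whose `risk` field holds the reduction.
#' @export
absolute_risk_reduction <- function(risk_bau, risk_iat) {
  stopifnot(inherits(risk_bau, "risk_curve"), inherits(risk_iat, "risk_curve"))
  check_same_grid(risk_bau$age, risk_iat$age)
  structure(list(age = risk_bau$age, risk = risk_bau$risk - risk_iat$risk),
            class = "risk_curve")
}

#' Number of cohort members who contract the disease
#'
#' `C = N0 * integral i(tau) (1 - p(tau)) S(tau) dtau` over the life span:
#' the incidence applied to the healthy share of survivors, scaled to the
#' cohort size.
#'
#' @param i incidence: `age_course` or numeric vector on the grid of `S`.
#' @param p prevalence: `prevalence_path` or numeric vector.
#' @param S a [survival_path()].
#' @param N0 cohort size at birth.
#' @param onset_age optional onset age, see [lifetime_risk()].
#' @return number of cases (persons), in `[0, N0]`.
#' @export
case_count <- function(i, p, S, N0, onset_age = NULL) {
  stopifnot(inherits(S, "survival_path"), is.finite(N0), N0 > 0)
  ages <- S$age
  i <- course_values(i, ages, lower_open = TRUE)
  p <- path_values(p, ages)
  check_same_length(i, p, S$surv)
  C <- cum_onset(ages, i * (1 - p) * S$surv, onset_age)
  N0 * C[length(C)]
}

#' Cases prevented by the intervention
#'
#' The number of cases averted by the intervention scenario, computed as the
#' single integral
#' \deqn{\Delta C = N_0 \int \{ i_{BAU}(1 - p_{BAU}) - i_{IAT}(1 - p_{IAT}) \} S \, d\tau,}
#' together with the prevented fraction `Delta C / C_BAU`. Both scenarios
#' share the survival function (the general mortality is not altered by the
#' intervention).
#'
#' @param i_bau,i_iat incidence courses (or grid vectors) of the two scenarios.
#' @param p_bau,p_iat the matching prevalence paths.
#' @param S shared [survival_path()].
#' @param N0 cohort size at birth.
#' @param onset_age optional onset age, see [lifetime_risk()].
#' @return list with `cases_bau`, `cases_iat`, `delta_cases` (persons) and
#'   `prevented_fraction` (proportion of BAU cases averted).
#' @export
prevented_cases <- function(i_bau, p_bau, i_iat, p_iat, S, N0,
                            onset_age = NULL) {
  stopifnot(inherits(S, "survival_path"))
  ages <- S$age
  ib <- course_values(i_bau, ages, lower_open = TRUE)
  pb <- path_values(p_bau, ages)
  ii <- course_values(i_iat, ages, lower_open = TRUE)
  pi_ <- path_values(p_iat, ages)
  check_same_length(ib, pb, ii, pi_, S$surv)
  D <- cum_onset(ages, (ib * (1 - pb) - ii * (1 - pi_)) * S$surv, onset_age)
  delta <- N0 * D[length(D)]
  cb <- case_count(ib, pb, S, N0, onset_age)
  ci <- case_count(ii, pi_, S, N0, onset_age)
  if (cb <= 0) stop("no cases under business as usual: prevented fraction undefined")
  list(cases_bau = cb, cases_iat = ci, delta_cases = delta,
       prevented_fraction = delta / cb)
}

#' Disease-free life expectancy (Sullivan's method)
#'
#' Expected years lived free of the disease after age `a`, conditional on
#' being alive at `a`:
#' \deqn{e_{DF}(a) = \frac{1}{S(a)} \int_a^{a_{max}} (1 - p(u))\, S(u)\, du.}
#' The improper upper limit is truncated at the grid's maximum age, where
#' survival is numerically negligible for realistic mortality.
#'
#' @param p prevalence: `prevalence_path` or numeric vector on the grid of `S`.
#' @param S a [survival_path()].
#' @param a conditioning age (years), strictly inside the grid.
#' @return years, between 0 and the remaining life expectancy at `a`.
#' @export
disease_free_life_expectancy <- function(p, S, a) {
  stopifnot(inherits(S, "survival_path"))
  ages <- S$age
  if (a < min(ages) || a >= max(ages)) stop("'a' must lie inside the age grid")
  p <- path_values(p, ages)
  Sa <- curve_at(S, a)
  if (Sa <= 0) stop("survival at the conditioning age is zero")
  keep <- ages >= a
  gr_ages <- c(a, ages[keep & ages > a])
  integrand <- (1 - p) * S$surv
  gr_vals <- c(stats::approx(ages, integrand, xout = a)$y,
               integrand[keep & ages > a])
  trapz_grid(gr_ages, gr_vals) / Sa
}

#' Gain in disease-free life expectancy between scenarios
#'
#' Difference of the Sullivan estimates at the onset age,
#' `e_DF,IAT(onset) - e_DF,BAU(onset)`; non-negative whenever the
#' intervention lowers incidence. Conditioning at the onset age is natural
#' because no one has the disease before it.
#'
#' @param p_bau,p_iat prevalence paths of the two scenarios.
#' @param S shared [survival_path()].
#' @param onset_age conditioning age (default 35).
#' @return list with `ef_bau`, `ef_iat` (years at the conditioning age),
#'   `delta` (years gained) and `relative_gain` (`delta / ef_bau`).
#' @export
delta_disease_free <- function(p_bau, p_iat, S, onset_age = 35) {
  eb <- disease_free_life_expectancy(p_bau, S, onset_age)
  ei <- disease_free_life_expectancy(p_iat, S, onset_age)
  list(ef_bau = eb, ef_iat = ei, delta = ei - eb, relative_gain = (ei - eb) / eb)
}

#' Full scenario contrast for one sex
#'
#' Runs the whole analytic chain for a BAU / intervention pair: solves both
#' prevalence paths, decomposes mortality per scenario, and computes the
#' lifetime-risk curves, absolute risk reduction, case counts, prevented
#' fraction, and the Sullivan disease-free quantities.
#'
#' @param bau,iat [scenario_inputs()] for the two arms; must agree in sex,
#'   onset age, cohort size and share the general and relative mortality.
#' @param grid_step,a_max numerical grid, see [solve_cohort_prevalence()].
#' @param report_ages ages at which scalar risks are tabulated
#'   (default `c(40, 50, 60, 70, 80, 90)`).
#' @param check run the solver's convergence self-check (default `TRUE`;
#'   turn off inside long Monte-Carlo loops).
#' @return An object of class `"outcome_set"`.
#' @export
scenario_contrast <- function(bau, iat, grid_step = 0.05, a_max = 110,
                              report_ages = c(40, 50, 60, 70, 80, 90),
                              check = TRUE) {
  stopifnot(inherits(bau, "scenario_inputs"), inherits(iat, "scenario_inputs"))
  if (bau$sex != iat$sex) stop("scenario arms must describe the same sex")
  if (bau$onset_age != iat$onset_age) stop("scenario arms must share the onset age")

  ages <- seq(0, a_max, by = grid_step)
  pb <- solve_cohort_prevalence(bau, grid_step, a_max, check = check)
  pi_ <- solve_cohort_prevalence(iat, grid_step, a_max, check = check)

  m <- course_values(bau$general_mortality, ages)
  R <- course_values(bau$relative_mortality, ages)
  m0_b <- m / (1 + pb$prevalence * (R - 1))
  m0_i <- m / (1 + pi_$prevalence * (R - 1))

  risk_b <- lifetime_risk(bau$incidence, m0_b, ages, bau$onset_age)
  risk_i <- lifetime_risk(iat$incidence, m0_i, ages, iat$onset_age)
  arr <- absolute_risk_reduction(risk_b, risk_i)

  S <- survival_path(m, ages)
  pc <- prevented_cases(bau$incidence, pb, iat$incidence, pi_, S,
                        bau$cohort_size, bau$onset_age)
  df <- delta_disease_free(pb, pi_, S, bau$onset_age)

  tab <- data.frame(
    sex = bau$sex,
    age = report_ages,
    risk_bau = curve_at(risk_b, report_ages),
    risk_iat = curve_at(risk_i, report_ages),
    arr = curve_at(arr, report_ages)
  )

  structure(list(
    sex = bau$sex,
    prevalence_bau = pb, prevalence_iat = pi_,
    risk_bau = risk_b, risk_iat = risk_i, arr = arr,
    survival = S,
    cases_bau = pc$cases_bau, cases_iat = pc$cases_iat,
    delta_cases = pc$delta_cases, prevented_fraction = pc$prevented_fraction,
    ef_bau = df$ef_bau, ef_iat = df$ef_iat,
    delta_disease_free = df$delta, relative_gain = df$relative_gain,
    risk_table = tab,
    grid_step = grid_step, a_max = a_max
  ), class = "outcome_set")
}

#' @export
print.outcome_set <- function(x, digits = 3, ...) {
  cat(sprintf("scenario contrast (%s):\n", x$sex))
  cat(sprintf("  prevented cases: %.0f of %.0f (%.1f%%)\n",
              x$delta_cases, x$cases_bau, 100 * x$prevented_fraction))
  cat(sprintf("  disease-free life expectancy at %g: %.2f -> %.2f years (+%.2f, +%.1f%%)\n",
              x$prevalence_bau$onset_age, x$ef_bau, x$ef_iat,
              x$delta_disease_free, 100 * x$relative_gain))
  cat("  lifetime risk (%):\n")
  tab <- x$risk_table
  tab[, c("risk_bau", "risk_iat", "arr")] <-
    round(100 * tab[, c("risk_bau", "risk_iat", "arr")], 1)
  print(tab, row.names = FALSE)
  invisible(x)
}

check_same_grid <- function(a1, a2) {
  if (length(a1) != length(a2) || any(abs(a1 - a2) > 1e-9)) {
    stop("curves are not on the same age grid")
  }
}

check_same_length <- function(...) {
  n <- lengths(list(...))
  if (length(unique(n)) != 1L) stop("inputs are not on a common age grid")
}
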