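#' Tabulated age-specific rate schedule
#'
#' An age -> rate mapping on a strictly increasing age grid, used for
#' incidence and mortality rates (per person-year). Off-grid ages inside the
#' grid range are interpolated linearly on the log-rate scale (rates are
#' positive and multiplicative in nature); on segments where a grid value is
#' zero the interpolation falls back to the linear scale. Evaluation outside
#' the grid range is an error: extrapolation is the job of the parametric
#' shapes ([log_parabola()], [log_line()], [gompertz_makeham()]).
#'
#' @param age numeric vector of grid ages in years, strictly increasing,
#'   all `>= 0`.
#' @param rate numeric vector of rates per person-year at each grid age;
#'   finite and non-negative.
#' @return An object of class `"rate_schedule"` (also an `"age_course"`).
#' @seealso [rate_at()] for evaluation, [read_rate_table()] for the CSV form.
#' @examples
#' m <- rate_schedule(c(0, 50, 100), c(0.001, 0.005, 0.4))
#' rate_at(m, c(0, 25, 75))
#' @export
rate_schedule <- function(age, rate) {
  age <- as.numeric(age)
  rate <- as.numeric(rate)
  if (length(age) < 2L) stop("a rate schedule needs at least two grid ages")
  if (length(age) != length(rate)) stop("'age' and 'rate' must have equal length")
  if (anyNA(age) || anyNA(rate) || any(!is.finite(rate))) {
    stop("rate schedule contains missing or non-finite entries")
  }
  if (any(diff(age) <= 0)) stop("grid ages must be strictly increasing")
  if (any(age < 0)) stop("grid ages must be non-negative")
  if (any(rate < 0)) {
    stop("negative rate at age ", age[which(rate < 0)[1L]])
  }
  structure(list(age = age, rate = rate),
            class = c("rate_schedule", "age_course"))
}

#' Log-parabolic age course
#'
#' Parametric incidence shape `i(a) = exp(c0 + c1 a + c2 a^2)`. With `c2 < 0`
#' the log-incidence rises and then falls with age, the pattern seen for
#' adult-onset chronic diseases such as type 2 diabetes in registry data.
#'
#' @param c0,c1,c2 real coefficients of the parabola in log-rate space.
#' @return An object of class `"log_parabola"` / `"age_course"`.
#' @export
log_parabola <- function(c0, c1, c2) {
  stopifnot(is.finite(c0), is.finite(c1), is.finite(c2))
  structure(list(c0 = c0, c1 = c1, c2 = c2),
            class = c("log_parabola", "age_course"))
}

#' Log-linear age course
#'
#' Parametric relative-mortality shape `R(a) = exp(d0 + d1 a)`. Registry data
#' typically show the mortality ratio of diseased to non-diseased persons
#' declining with age, i.e. `d1 < 0`.
#'
#' @param d0,d1 real coefficients of the line in log space.
#' @return An object of class `"log_line"` / `"age_course"`.
#' @export
log_line <- function(d0, d1) {
  stopifnot(is.finite(d0), is.finite(d1))
  structure(list(d0 = d0, d1 = d1), class = c("log_line", "age_course"))
}

#' Gompertz-Makeham mortality hazard
#'
#' All-cause mortality `m(a) = lambda + phi * exp(theta * a)`: an
#' age-independent background rate plus an exponentially increasing
#' senescent component. Standard parametric form for adult general mortality.
#'
#' @param lambda background (Makeham) rate, `>= 0`, per person-year.
#' @param phi level of the Gompertz component at age 0, `> 0`.
#' @param theta log-slope of the Gompertz component per year of age, `>= 0`.
#' @return An object of class `"gompertz_makeham"` / `"age_course"`.
#' @export
gompertz_makeham <- function(lambda, phi, theta) {
  if (lambda < 0) stop("'lambda' must be non-negative")
  if (phi <= 0) stop("'phi' must be positive")
  if (theta < 0) stop("'theta' must be non-negative")
  structure(list(lambda = lambda, phi = phi, theta = theta),
            class = c("gompertz_makeham", "age_course"))
}

#' Constant age course
#'
#' @param value the rate (or ratio), a single non-negative finite number.
#' @return An object of class `"constant_course"` / `"age_course"`.
#' @export
constant_course <- function(value) {
  stopifnot(length(value) == 1L, is.finite(value), value >= 0)
  structure(list(value = value), class = c("constant_course", "age_course"))
}

#' Evaluate an age course
#'
#' Generic evaluator: every rate representation in the package (tabulated
#' schedule, parametric shape, intervention-scaled or onset-truncated
#' wrapper) answers `rate_at(x, age)` with a vector of non-negative rates.
#'
#' @param x an `age_course` object.
#' @param age numeric vector of ages (years).
#' @param ... passed on to methods. The onset-cutoff wrapper understands
#'   `lower_open = TRUE`, which zeroes the rate only strictly below the
#'   onset age (right-continuous evaluation, used internally by the solver
#'   and the quadratures, which start exactly at the onset age).
#' @return numeric vector of rates, same length as `age`.
#' @export
rate_at <- function(x, age, ...) UseMethod("rate_at")

#' @export
rate_at.rate_schedule <- function(x, age, ...) {
  if (anyNA(age)) stop("'age' contains NA")
  lo <- min(x$age); hi <- max(x$age)
  if (any(age < lo) || any(age > hi)) {
    bad <- age[age < lo | age > hi][1L]
    stop(sprintf(
      "age %.6g outside the schedule's grid range [%g, %g]; use a parametric shape to extrapolate",
      bad, lo, hi))
  }
  idx <- findInterval(age, x$age, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(x$age) - 1L)
  a0 <- x$age[idx];  a1 <- x$age[idx + 1L]
  r0 <- x$rate[idx]; r1 <- x$rate[idx + 1L]
  w <- (age - a0) / (a1 - a0)
  pos <- r0 > 0 & r1 > 0
  out <- numeric(length(age))
  out[pos] <- exp((1 - w[pos]) * log(r0[pos]) + w[pos] * log(r1[pos]))
  out[!pos] <- (1 - w[!pos]) * r0[!pos] + w[!pos] * r1[!pos]
  out
}

#' @export
rate_at.log_parabola <- function(x, age, ...) exp(x$c0 + x$c1 * age + x$c2 * age^2)

#' @export
rate_at.log_line <- function(x, age, ...) exp(x$d0 + x$d1 * age)

#' @export
rate_at.gompertz_makeham <- function(x, age, ...) x$lambda + x$phi * exp(x$theta * age)

#' @export
rate_at.constant_course <- function(x, age, ...) rep(x$value, length(age))

#' @export
print.age_course <- function(x, ...) {
  cls <- class(x)[1L]
  switch(cls,
    rate_schedule = cat(sprintf(
      "rate schedule on %d ages in [%g, %g]\n", length(x$age),
      min(x$age), max(x$age))),
    log_parabola = cat(sprintf(
      "log-parabolic course: log r(a) = %.4g + %.4g a + %.4g a^2\n",
      x$c0, x$c1, x$c2)),
    log_line = cat(sprintf(
      "log-linear course: log r(a) = %.4g + %.4g a\n", x$d0, x$d1)),
    gompertz_makeham = cat(sprintf(
      "Gompertz-Makeham hazard: m(a) = %.4g + %.4g exp(%.4g a)\n",
      x$lambda, x$phi, x$theta)),
    constant_course = cat(sprintf("constant course: %g\n", x$value)),
    cat(sprintf("<%s age course>\n", cls))
  )
  invisible(x)
}

#' Remove disease incidence below the onset age
#'
#' Adult-onset diseases are modelled as impossible up to an onset age (for
#' type 2 diabetes, 35 years): the returned course is 0 for ages `<=
#' onset_age` and unchanged above. The cutoff is idempotent and commutes
#' with [apply_intervention()].
#'
#' @param x an `age_course` for the incidence.
#' @param onset_age years, `>= 0`.
#' @return An `age_course` wrapping `x`.
#' @export
enforce_onset_cutoff <- function(x, onset_age) {
  stopifnot(inherits(x, "age_course"), is.finite(onset_age), onset_age >= 0)
  if (inherits(x, "onset_cutoff")) {
    x$onset_age <- max(x$onset_age, onset_age)
    return(x)
  }
  structure(list(course = x, onset_age = onset_age),
            class = c("onset_cutoff", "age_course"))
}

#' @export
rate_at.onset_cutoff <- function(x, age, lower_open = FALSE, ...) {
  out <- rate_at(x$course, age, lower_open = lower_open, ...)
  if (lower_open) out[age < x$onset_age] <- 0
  else out[age <= x$onset_age] <- 0
  out
}

#' Scale an incidence course by an intervention's relative risk reduction
#'
#' The intervention scenario assumes the incidence is reduced by a relative
#' risk reduction `h`, i.e. `i_intervention(a) = (1 - h) * i(a)` at every
#' age. Any onset-age cutoff present in `x` is preserved.
#'
#' @param x the incidence `age_course`.
#' @param h relative risk reduction in `[0, 1)`; `h = 0` returns a course
#'   equivalent to `x`.
#' @return An `age_course` wrapping `x`.
#' @export
apply_intervention <- function(x, h) {
  stopifnot(inherits(x, "age_course"))
  if (!is.finite(h) || h < 0 || h >= 1) {
    stop("relative risk reduction 'h' must lie in [0, 1)")
  }
  structure(list(course = x, factor = 1 - h),
            class = c("scaled_course", "age_course"))
}

#' @export
rate_at.scaled_course <- function(x, age, ...) x$factor * rate_at(x$course, age, ...)

#' Decompose general mortality into state-specific mortalities
#'
#' In the illness-death model the general mortality is the prevalence-weighted
#' mixture `m = p m1 + (1 - p) m0` of the mortality of the diseased (`m1`)
#' and the non-diseased (`m0`), with relative mortality `R = m1 / m0`.
#' Inverting the mixture gives `m0 = m / (1 + p (R - 1))` and `m1 = R m0`.
#'
#' @param m general mortality: an `age_course` or a numeric vector on `ages`.
#' @param R relative mortality: `age_course` or numeric vector.
#' @param p prevalence: a [solve_cohort_prevalence()] result, an `age_course`,
#'   or a numeric vector of proportions on `ages`.
#' @param ages the common age grid on which to decompose.
#' @return list with `m0` and `m1`, both [rate_schedule()]s on `ages`.
#' @export
decompose_mortality <- function(m, R, p, ages) {
  m <- course_values(m, ages)
  R <- course_values(R, ages)
  p <- path_values(p, ages)
  denom <- 1 + p * (R - 1)
  if (any(denom <= 0)) {
    stop("degenerate mortality decomposition: 1 + p (R - 1) <= 0 at age ",
         ages[which(denom <= 0)[1L]])
  }
  m0 <- m / denom
  list(m0 = rate_schedule(ages, m0), m1 = rate_schedule(ages, R * m0))
}

#' Back-calculate the relative mortality from observable quantities
#'
#' Given the mortality of the diseased `m1`, the prevalence `p` and the
#' general mortality `m` — the quantities a cohort study actually reports —
#' the relative mortality is `R = m1 (1 - p) / (m - p m1)`. This is the
#' exact inverse of [decompose_mortality()].
#'
#' @param m1 mortality rate of the diseased (numeric, vectorised).
#' @param p prevalence proportion(s), in `[0, 1)`.
#' @param m general mortality rate(s).
#' @return numeric vector of relative mortalities, `> 0`.
#' @export
relative_mortality_from_inputs <- function(m1, p, m) {
  stopifnot(all(is.finite(m1)), all(is.finite(p)), all(is.finite(m)))
  if (any(p < 0 | p >= 1)) stop("'p' must lie in [0, 1)")
  denom <- m - p * m1
  if (any(denom <= 0)) {
    stop("epidemiologically inconsistent inputs: m - p * m1 must be positive")
  }
  m1 * (1 - p) / denom
}

#' Calibrate a log-parabolic incidence to anchor observations
#'
#' Proportional-hazards calibration of a reference population's incidence
#' shape to the target population: the target incidence is assumed to be
#' `beta` times the reference at every age, i.e. a constant vertical offset
#' `log beta` in log-rate space. The offset is the least-squares estimate
#' over the anchors, `log beta = mean(log i_obs - log i_ref)` — the log of
#' the geometric mean of the observed/reference ratios. Curvature (`c1`,
#' `c2`) is taken from the reference.
#'
#' @param reference a [log_parabola()] reference shape.
#' @param age anchor ages (years), at least one.
#' @param incidence observed incidence at the anchor ages, all `> 0`.
#' @return list with `shape` (the calibrated [log_parabola()]) and `beta`.
#' @export
fit_log_parabola_offset <- function(reference, age, incidence) {
  stopifnot(inherits(reference, "log_parabola"))
  off <- log_offset(reference, age, incidence)
  list(shape = log_parabola(reference$c0 + off, reference$c1, reference$c2),
       beta = exp(off))
}

#' Calibrate a log-linear relative mortality to anchor observations
#'
#' Analogue of [fit_log_parabola_offset()] for the relative mortality: the
#' target is `gamma` times the reference log-line, slope preserved.
#'
#' @param reference a [log_line()] reference shape.
#' @param age anchor ages (years).
#' @param relative_mortality observed relative mortality at the anchors, `> 0`.
#' @return list with `shape` (the calibrated [log_line()]) and `gamma`.
#' @export
fit_log_line_offset <- function(reference, age, relative_mortality) {
  stopifnot(inherits(reference, "log_line"))
  off <- log_offset(reference, age, relative_mortality)
  list(shape = log_line(reference$d0 + off, reference$d1), gamma = exp(off))
}

log_offset <- function(reference, age, obs) {
  if (length(age) == 0L) stop("at least one anchor observation is required")
  if (length(age) != length(obs)) stop("'age' and observations differ in length")
  if (any(!is.finite(obs)) || any(obs <= 0)) {
    stop("anchor observations must be positive and finite")
  }
  mean(log(obs) - log(rate_at(reference, age)))
}

# Internal: evaluate a course given either an age_course or a numeric vector
# already on the grid.
course_values <- function(x, ages, ...) {
  if (inherits(x, "age_course")) return(rate_at(x, ages, ...))
  x <- as.numeric(x)
  if (length(x) == 1L) return(rep(x, length(ages)))
  if (length(x) != length(ages)) stop("numeric course does not match the age grid")
  x
}

# Internal: prevalence values on the grid from a prevalence_path, an
# age_course, a scalar or a vector.
path_values <- function(p, ages) {
  if (inherits(p, "prevalence_path")) {
    if (length(p$age) == length(ages) && all(abs(p$age - ages) < 1e-9)) {
      return(p$prevalence)
    }
    return(stats::approx(p$age, p$prevalence, xout = ages, rule = 1)$y)
  }
  if (inherits(p, "age_course")) return(rate_at(p, ages))
  p <- as.numeric(p)
  if (length(p) == 1L) return(rep(p, length(ages)))
  if (length(p) != length(ages)) stop("prevalence vector does not match the age grid")
  p
}
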