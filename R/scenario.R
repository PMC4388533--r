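#' Assemble the rate inputs for one sex and one scenario
#'
#' Bundles everything the prevalence solver needs for a single birth cohort
#' arm: the incidence course (the onset-age cutoff is applied here if not
#' already present), the general mortality, the relative mortality of the
#' diseased, and cohort metadata.
#'
#' @param incidence incidence `age_course` (per person-year).
#' @param general_mortality all-cause mortality `age_course`.
#' @param relative_mortality relative mortality `age_course` (ratio
#'   `m1 / m0`, dimensionless).
#' @param sex `"male"` or `"female"`.
#' @param scenario `"BAU"` (business as usual) or `"IAT"` (intervention).
#' @param onset_age age in years below which the disease does not occur;
#'   default 35 (adult-onset type 2 diabetes).
#' @param birth_year calendar year of birth of the cohort (metadata only:
#'   no rate in the model carries a calendar-time trend). Default 1985.
#' @param cohort_size number of cohort members at birth, `> 0`.
#' @return An object of class `"scenario_inputs"`.
#' @export
scenario_inputs <- function(incidence, general_mortality, relative_mortality,
                            sex = c("male", "female"),
                            scenario = c("BAU", "IAT"),
                            onset_age = 35, birth_year = 1985,
                            cohort_size = 1e5) {
  sex <- match.arg(sex)
  scenario <- match.arg(scenario)
  stopifnot(inherits(incidence, "age_course"),
            inherits(general_mortality, "age_course"),
            inherits(relative_mortality, "age_course"),
            is.finite(onset_age), onset_age >= 0,
            is.finite(cohort_size), cohort_size > 0)
  structure(list(
    incidence = enforce_onset_cutoff(incidence, onset_age),
    general_mortality = general_mortality,
    relative_mortality = relative_mortality,
    sex = sex, scenario = scenario,
    onset_age = onset_age, birth_year = birth_year,
    cohort_size = cohort_size
  ), class = "scenario_inputs")
}

#' @export
print.scenario_inputs <- function(x, ...) {
  cat(sprintf("scenario inputs: %s, %s; onset age %g, cohort of %g born %d\n",
              x$sex, x$scenario, x$onset_age, x$cohort_size, x$birth_year))
  invisible(x)
}
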