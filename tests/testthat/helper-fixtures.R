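# Scenario inputs with constant rates, the workhorse of the closed-form and
# oracle tests.
const_inputs <- function(i, m, R, onset_age = 0, scenario = "BAU",
                         cohort_size = 1e5) {
  scenario_inputs(constant_course(i), constant_course(m), constant_course(R),
                  sex = "male", scenario = scenario,
                  onset_age = onset_age, cohort_size = cohort_size)
}

# Default synthetic study with noise-free anchors (exactly consistent truth).
clean_study <- function(...) {
  synthetic_study(synthetic_config(...), noise_sd = 0)
}

# Decompose a solved scenario into (i, m0, m1) schedules that drive the
# microsimulation oracle.
sim_rates_from_scenario <- function(inputs, grid_step = 0.1, a_max = 110) {
  path <- solve_cohort_prevalence(inputs, grid_step, a_max, check = FALSE)
  dec <- decompose_mortality(inputs$general_mortality,
                             inputs$relative_mortality, path, path$age)
  list(path = path, m0 = dec$m0, m1 = dec$m1, inputs = inputs)
}
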