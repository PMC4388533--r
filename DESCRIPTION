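Package: illnessdeath
Title: Illness-Death Model Projections of Chronic Disease Burden in Birth Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects the age-specific prevalence of an irreversible chronic
    disease in a birth cohort from its incidence, the general mortality of the
    population and the relative mortality of the diseased, using the
    illness-death multistate model. Along a cohort line the prevalence obeys
    an ordinary differential equation which is integrated with a fixed-step
    fourth-order Runge-Kutta scheme. From the solved prevalence the package
    computes the lifetime risk of disease under competing mortality, the
    number of cases prevented by an incidence-lowering intervention, and the
    disease-free life expectancy by Sullivan's method, contrasting a
    business-as-usual scenario with an intervention scenario. Input
    uncertainty is propagated by Monte-Carlo resampling of anchor-age rate
    observations combined with proportional-hazards calibration against
    log-parabolic incidence and log-linear relative-mortality reference
    shapes, and confidence intervals are obtained with the bias-corrected and
    accelerated (BCa) bootstrap. A stochastic individual-level cohort
    microsimulation of the same three-state model serves as an independent
    validator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
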