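Package: audmc
Title: Two-State Continuous-Time Markov Modelling of Alcohol Use Disorder
    Transitions in Panel Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models transitions into and out of alcohol use disorder (AUD)
    observed in longitudinal panel cohorts as a two-state continuous-time
    Markov chain whose transition intensities depend log-linearly on
    pre-transition covariates. Provides panel-data restructuring into
    transition pairs, maximum-likelihood fitting with analytic gradients,
    covariate state-dependence testing with likelihood-ratio tests and a
    constraint-selection rule, age-stratified adjusted models reported as
    hazard-ratio tables, a Pearson-type lack-of-fit statistic with a
    parametric-bootstrap p-value, and a synthetic cohort generator that
    emulates a biannual five-wave emergency-department cohort design with
    AR(1) time-varying covariates and wave-level missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
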