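Package: u5msmooth
Title: Subnational Under-Five Mortality Estimation from Birth Histories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates under-five mortality (U5M) at subnational
    administrative units from survey and census birth histories. Implements
    the synthetic-cohort direct estimator for complete birth histories,
    Brass-type cohort and period indirect estimators for summary birth
    histories (indexed by maternal age or time since first birth) with a
    least-squares calibration routine, and a Bayesian spatio-temporal
    smoother that fuses all per-survey, per-method county-year estimates
    through a separable conditionally autoregressive (space) by AR(1)
    (time) Gaussian process fitted by Markov chain Monte Carlo. Includes a
    synthetic birth-history generator for fully reproducible testing,
    hold-out cross-validation, and metrics for mortality-reduction targets
    (annual rate of reduction, projections, goal assessment) and
    between-county inequality.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Matrix
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
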