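Package: dyadtrack
Title: Simulation and Analysis of Dyadic Haptic Tracking Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pairs of linear-quadratic-Gaussian tracking agents whose
    wrists are coupled by a virtual elastic band, under three interaction
    strategies: follow-the-leader, interpersonal goal integration, and
    neuromechanical goal sharing (goal integration with stiffness-dependent
    haptic channel noise calibrated from haptic-only tracking). Provides the
    experiment's target and trial-schedule generators, partner-policy
    identification by extended Kalman filtering, trial metrics (tracking
    error, improvement, relative error, interaction effort), a synthetic
    dyad-data generator, and the mixed-effects / repeated-measures ANOVA
    statistical pipeline used to compare interaction models against data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    car,
    emmeans,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
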