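Package: extinctrl
Title: Computational Analysis of Threat Extinction Learning
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for model-based analysis of fear extinction
    experiments: three-day conditioning trial schedules (acquisition,
    extinction, retrieval with reinstatement), a Rescorla-Wagner/Pearce-Hall
    hybrid learning model fitted to trial-wise binary US-expectancy ratings
    by maximum likelihood, model-derived prediction-error and associability
    parametric modulators for first-level fMRI GLMs with a canonical
    double-gamma HRF, range-corrected skin-conductance and fear-rating
    contrasts, and causal mediation analysis (quasi-Bayesian and bootstrap
    average causal mediation effects). Includes a synthetic-cohort generator
    with known ground truth so every stage is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
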