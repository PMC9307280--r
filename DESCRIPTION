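Package: cowsim
Title: Closed-Loop Cerebral Hemodynamics, Surrogate Modelling and Uncertainty Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-loop one-dimensional--zero-dimensional (1D-0D) blood flow
    simulator of the systemic arterial tree including the circle of Willis,
    with an empirical stenosis pressure-loss model, three-element Windkessel
    outlets and a time-varying elastance heart.  On top of the solver the
    package provides uniform sampling of anatomical/physiological input
    vectors, a fully connected neural-network surrogate trained on simulated
    cycle-averaged flows and pressures, iterative calibration of cerebral
    peripheral resistances to measured flows, Monte Carlo uncertainty
    quantification of the postoperative flow-rate increase after virtual
    stenosis dilation (cerebral hyperperfusion risk), and variance-based
    Sobol sensitivity analysis with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
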