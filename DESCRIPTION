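Package: ecomotor
Title: Hierarchical Success-Efficient/Failure-Safe Motor Learning Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-body squat-to-stand motor adaptation under a
    velocity-proportional backward perturbation with a two degree-of-freedom
    inverted-pendulum body. A hierarchical learning architecture combines
    ecological cost switching between safety and movement efficiency,
    policy-gradient search over via-point motor plans, online adaptation of an
    inverse-dynamics internal model, and prediction-error-driven feedback gain
    scaling. Includes the accompanying analysis battery: trajectory-area and
    dimensionless-jerk adaptation metrics, EMG co-contraction processing,
    exponential learning-curve fitting with plateau detection, outcome-
    conditioned contrasts, and run-versus-reference correlation tables, plus a
    synthetic fixture generator for human-like trial series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
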