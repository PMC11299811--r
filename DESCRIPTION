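Package: ldcm
Title: Low-Dimensional Confidence Model for Drift-Diffusion Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, fitting and comparison of the low-dimensional
    confidence (LDC) model, a tractable two-parameter logistic approximation
    of the Bayesian probability-correct readout in drift-diffusion decision
    making. Provides a discrete random-walk simulator with post-decisional
    evidence accumulation, quantile-proportion sum-of-squared-error fitting
    with a differential-evolution optimizer, BIC-based model comparison with
    random-effects Bayesian model selection, the statistical signatures of
    Bayesian confidence, and the model-generated trial-by-trial feedback
    algorithm.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
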