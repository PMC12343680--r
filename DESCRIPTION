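Package: fnstep
Title: In Silico Development of Functional Neuromuscular Stimulation Stepping Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for developing personalized functional
    neuromuscular stimulation (FNS) stepping patterns in silico. Provides a
    configurable planar muscle-actuated gait model with Hill-type
    muscle-tendon units and smoothed Hunt-Crossley foot-ground contact, a
    direct-collocation optimal-control transcription with a staged
    tracking-to-predictive solution cascade, compilation of optimized muscle
    excitations into device-ready pulse-width stimulation schedules with
    frequency scheduling and charge accounting, synthetic generators for
    neurotypical-style reference data and instrumented stepping trials, and
    a gait-trial analysis pipeline (zero-lag filtering, interquartile-range
    outlier rejection, stride normalization, step and upper-extremity-effort
    metrics, and statistics) for comparing optimized against manually tuned
    patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    Matrix,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
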