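Package: pfic
Title: Parametric Feedback Inhibition Control Modelling of Cortical
    Excitation-Inhibition Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates coupled excitatory-inhibitory neural-mass dynamics on a
    structural connectome with automatic feedback inhibition control (FIC),
    parameterizes regional synaptic parameters as linear combinations of
    cortical anatomical and functional gradients (the pFIC scheme), fits the
    resulting ten-dimensional parameter vector to empirical functional
    connectivity (FC) and FC dynamics (FCD) with a covariance matrix
    adaptation evolution strategy, and derives the regional
    excitation-inhibition (E/I) ratio marker together with group-level
    developmental and cognitive statistics (age regressions, matched-group
    contrasts, FDR correction, spatial spin tests, and permutation group
    tests). Includes a synthetic-fixtures generator so the full pipeline is
    testable on parameter-recovery studies without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
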