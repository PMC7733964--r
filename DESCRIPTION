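Package: discofit
Title: Single-Cell Ensemble Modeling and Network Inference for Signaling
    Snapshot Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-cell signaling snapshot data of the
    kind produced by mass cytometry: synthetic snapshot generation with known
    ground truth, viability filtering and phenotype gating, full-order
    partial-correlation network inference, a unified power-law (generalized
    mass action) ODE model of the EGF-driven ERK and AKT pathways with
    cell-specific deactivation rates closed algebraically from baseline
    measurements, distribution-matching parameter estimation by minimising
    the maximum mean discrepancy between simulated and measured multivariate
    snapshot distributions, grid-based parameter sensitivity analysis, and
    constrained reconciliation of parameter sets fitted to different cell
    phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
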