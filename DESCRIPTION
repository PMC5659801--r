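Package: epoRtraffic
Title: Single-Cell Ensemble Modelling of Erythropoietin Receptor Trafficking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation models of erythropoietin receptor
    (EpoR) trafficking between the plasma membrane and intracellular
    compartments, fitted jointly to ensembles of single-cell fluorescence
    time courses. Provides the basic trafficking model and its sixteen
    structural variants (optional recycling and degradation routes),
    reduced models for photobleaching and cycloheximide experiments,
    cell-ensemble parameter estimation with distribution-constraint
    penalties, corrected-AIC model discrimination, profile-likelihood
    confidence intervals, reaction-flux and concentration-control-coefficient
    analysis, multivariate log-normal sampling of cell-to-cell parameter
    variability, and a synthetic single-cell trajectory generator with the
    statistical structure of live-cell imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    lhs,
    MASS,
    Matrix,
    jsonlite,
    xml2,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
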