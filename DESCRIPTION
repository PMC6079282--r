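Package: neurofit
Title: Fitting Conductance-Based Neuron Models to Current-Clamp Data with
    CMA-ES
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automatic parameter optimization of multi-compartment,
    conductance-based neuron models against current-clamp recordings. Models
    are specified declaratively (channel kinetics, morphology as GENESIS .p or
    SWC files, per-region conductance densities in S/m^2); a compiled
    cable-equation integrator with Hodgkin-Huxley style channels and a
    single-exponential calcium pool produces voltage traces; a feature-based
    fitness function (spike shape, afterhyperpolarization, latency,
    subthreshold responses) compares simulation to data; and a bounded
    covariance matrix adaptation evolution strategy (CMA-ES) searches
    conductance densities and passive properties. Includes convergence
    detection, best-model selection, synthetic-recording generation for
    parameter-recovery validation, and post-hoc statistics (stepwise
    discriminant analysis, hierarchical and k-means clustering) that
    discriminate neuron subtypes from fitted parameters.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    parallel,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
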