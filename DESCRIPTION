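Package: pmfm
Title: Parametric Mean-Field Modelling of Whole-Brain Resting-State Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and inverts a connectome-coupled parametric dynamic
    mean-field model of resting-state brain activity. Regional circuit
    parameters (recurrent strength, external input, noise amplitude) are
    linear combinations of two cortical spatial maps (a T1w/T2w myelin-like
    map and a principal functional-connectivity gradient). Includes an
    Euler-Maruyama integrator with a Balloon-Windkessel haemodynamic forward
    model, static functional connectivity (FC) and FC-dynamics (FCD)
    observables, a CMA-ES model-inversion protocol with train/validation
    diversity selection, causal state-switching perturbation experiments,
    spin-test and random-gene-pair spatial statistics, and synthetic-data
    generators for all required inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    mclust,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
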