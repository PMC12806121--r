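Package: fadnet
Title: Fractional-Order Network Models of Alzheimer's Disease Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled amyloid-beta / tau / astrocyte dynamics with neuronal damage on
    brain-connectome graphs, under Caputo fractional-order (non-Markovian) time
    derivatives. Provides the five-variable heterodimer reaction model with a
    dual-role astrocyte compartment, equilibrium enumeration and integer/fractional
    stability classification, a fourth-order Runge-Kutta integrator and an
    Adams-Bashforth-Moulton predictor-corrector for Caputo systems, graph-Laplacian
    network diffusion built from fiber counts and lengths, toxic-protein seeding,
    mixed-tauopathy parameter heterogeneity, brain-ID/region averaging, a synthetic
    connectome generator, and Pearson-correlation global sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite, yaml, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
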