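Package: dcsflow
Title: Blood Flow Quantification for Diffuse Correlation Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward models, noise simulation, and inverse methods for
    diffuse correlation spectroscopy (DCS) measurements of blood flow.
    Provides analytical field autocorrelation solvers for semi-infinite and
    three-layer head geometries, a layered-slab photon Monte Carlo with
    momentum-transfer histories, a correlator noise model, classical
    Levenberg-Marquardt curve fitters, a compact one-dimensional
    convolutional network regressor for the coherence factor and blood flow
    index, and the evaluation experiments (relative-flow sweeps, intrinsic
    brain sensitivity, noise and optical-property robustness).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
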