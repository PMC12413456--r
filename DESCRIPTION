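Package: covrf
Title: Covariant Spatio-Temporal Receptive Fields for Event-Based Vision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and analysing covariant spatio-temporal
    receptive fields: scale-normalized affine Gaussian derivative kernels over
    space composed with time-causal truncated-exponential (leaky-integrator)
    and leaky integrate-and-fire dynamics over time. Includes numerical
    verification of the covariance properties under spatial affine, Galilean
    and temporal scaling transformations, a sparse event-camera simulator for
    moving and scaling shape contours, and a small scale-channel tracking
    network trained with backpropagation through time to quantify the benefit
    of receptive-field initialization over uniform initialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
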