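Package: spikeglm
Title: Poisson GLM Encoding and Decoding of Task-Structured Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mixed selectivity in trial-based
    electrophysiology recordings with Poisson generalized linear models.
    Simulates go/no-go virtual-corridor sessions with known ground-truth
    kernels, builds raised-cosine design matrices of event-based and
    tuning-based regressors, fits ridge-regularized maximum a posteriori
    encoding models with evidence-based hyperparameter selection and
    forward cross-validated model selection, quantifies per-variable
    contributions, decodes binary task variables from spikes by
    log-likelihood ratio and by linear classifiers, decomposes
    trial-averaged signal variance, and clusters neurons by their
    selectivity profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    Rcpp,
    glmnet,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
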