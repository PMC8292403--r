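Package: gravisyn
Title: Muscle Synergy Analysis of Walking Under Simulated Reduced Gravity
Version: 0.1.0
Authors@R:
    person("Gravisyn", "Developers", email = "gravisyn@example.org",
           role = c("aut", "cre"))
Description: Tools for modular analysis of lower-limb electromyography (EMG)
    recorded during treadmill walking under body-weight-support simulated
    reduced gravity. Implements linear-envelope EMG conditioning, gait-cycle
    segmentation from limb-axis kinematics and 200-bin time normalization,
    nonnegative matrix factorization (NMF) with cross-validated selection of
    the number of modules, cosine k-means clustering of modules across
    participants with cannot-link constraints across gravity levels,
    nonnegative CANDECOMP/PARAFAC tensor decomposition yielding
    condition-dependent module gains, module matching and bootstrap chance
    levels for similarity statistics, Froude-number walking-speed protocol
    utilities, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
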