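Package: escm
Title: Eigenvalue-Shrinkage One-Class Modelling for High-Dimensional
    Metabolomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-class classification ("is this new sample consistent with
    the reference class?") for high-dimensional feature tables such as
    untargeted LC-MS or NMR metabolomics data, where the number of variables
    P typically exceeds the number of reference samples N.  The classifier
    combines the squared Mahalanobis distance with linear eigenvalue-shrinkage
    estimators of the reference covariance matrix (Ledoit-Wolf, oracle
    approximating, and nonparametric Steinian intensities toward the identity
    target), and sets its critical limit from a scaled chi-square distribution
    moment-matched to leave-one-out cross-validated distances.  Also provides
    the classical F-based Mahalanobis limit for N > P, a van Wieringen ridge
    precision estimator, a PCA/SIMCA baseline with T2, Q and combined
    statistics, metabolite-table preprocessing (non-detect filtering,
    half-minimum imputation, log transform, auto-scaling), and a simulation
    framework for estimating type-I error and outlier-detection power under
    blocked correlation structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
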