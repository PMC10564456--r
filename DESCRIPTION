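Package: qgpredict
Title: Predicting Multivariate Phenotypic Evolution from Standing Genetic
    Variation and Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative-genetic analysis of multivariate phenotypic
    evolution in inbred-line panels. Estimates locomotion-behavior traits as
    transition rates of a continuous-time Markov chain from discretely
    observed movement-state tracks; fits multivariate (MANOVA) and univariate
    mixed models for phenotypic plasticity and divergence with canonical-axis
    (SSCP eigendecomposition) summaries; estimates Bayesian G-matrices and
    fitness-augmented G-matrices (selection differentials) with a blocked
    Gibbs sampler for the multivariate mixed model, including randomization
    nulls; compares covariance matrices by random skewers; and applies
    Lande's retrospective equation to obtain genetic and phenotypic selection
    gradients with posterior uncertainty, together with angle and magnitude
    diagnostics of predicted versus observed divergence. A synthetic-data
    generator with known ground truth (line panels, fitness, divergence
    vectors, Gillespie-simulated state tracks) supports validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    pracma,
    lme4,
    emmeans,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
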