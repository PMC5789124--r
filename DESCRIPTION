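Package: latentmarkov
Title: Latent Markov Models for Data-Driven Invariant Measure Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates invariant measures of Markovian systems from
    discretized time-series data.  Implements the classical Ulam pipeline
    (phase-space box discretization, transition counting, the empirical
    frequency estimator and its stationary eigenvector) together with a
    latent Markov model in which the transfer operator is factorized into
    two rectangular column-stochastic matrices through a K-dimensional
    unobserved categorical process.  The factors are fitted either by a
    hard clustering scheme (direct Bayesian model reduction) or by an
    expectation-maximisation algorithm (probabilistic latent semantic
    analysis); the invariant measure is obtained from the dominant
    eigenvector of the reduced K x K transfer operator and lifted back to
    the full state space.  Includes model selection by AIC, BIC and
    cross-validation, an overfitting bound on the latent dimension,
    nonparametric bootstrap confidence intervals, spectral analysis of
    metastability, and synthetic generators (a Lorenz-63 integrator,
    Markov chain samplers and planted latent models) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
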