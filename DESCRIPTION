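Package: oudecode
Title: Fisher Linear Discriminant Decoding of Leaky-Integrator Population Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form Fisher linear discriminant (LDA) readout error for a
    two-population leaky linear-integrator (Ornstein-Uhlenbeck) rate model with
    tunable noise correlation. Provides the stationary and transient moments of
    the integrator, an Euler-Maruyama (and exact-transition) trajectory
    simulator, the closed-form LDA weights, threshold and erfc error in both
    projection and Mahalanobis form, the maximal-error noise correlation
    (rho-star) and its single-parameter factorizations, a Monte-Carlo empirical
    decoder (stationary sampling, stratified train/test split, pooled-covariance
    LDA fit, held-out misclassification), scenario presets for the four
    canonical tuning configurations, parameter sweep utilities, and a registry
    of qualitative claims about how noise gain, leak and time constant shift
    the error-correlation curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    stats,
    utils,
    optparse
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
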