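Package: hlik
Title: Direct Hierarchical-Likelihood Estimation for Generalized Linear
    Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits generalized linear mixed models with crossed or nested
    random intercepts by direct maximization of Laplace-approximated
    adjusted profile likelihoods (hierarchical-likelihood inference).
    Implements the two-stage HL(1,1) REML estimator, the HL(0,1) joint
    shortcut, and maximum likelihood via the Laplace approximation, with
    sparse Newton inner optimization.  Includes adaptive Gauss-Hermite
    and tensor-grid quadrature oracles for verification, a simulator for
    electronic-health-record-like repeated-measures data with partially
    crossed patient and facility random effects, and a standardized-bias /
    mean-squared-error evaluation harness for method comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    splines,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
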