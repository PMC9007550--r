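Package: relcl
Title: Random Effects Latent Class Logit Models for Ranked Discrete Choice Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing ranked discrete
    choice experiments (DCEs) with a random effects latent class logit
    (RELCL) model. Includes construction of blocked, effects-coded choice
    designs with compound attributes; a synthetic-data generator with latent
    preference classes, covariate-dependent class membership and
    domain-specific standard-normal random effects; maximum-likelihood
    estimation of the rank-ordered (exploded) logit likelihood by EM with
    quasi-Newton refinement and multi-start, integrating random effects by
    Gauss-Hermite quadrature; BIC model selection over class and
    random-effect grids; and downstream analyses of posterior class
    membership, empirical-Bayes random-effect scores, individual-level
    preference distributions, bias-adjusted three-step covariate models and
    cross-model classification concordance.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    nnet,
    withr
Config/testthat/edition: 3
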