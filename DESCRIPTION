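Package: surgelite
Title: Unsupervised Discovery of Latent Contexts Modulating Genetic Effects on Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the SURGE model (Single-cell Unsupervised Regulation of
    Gene Expression): a probabilistic matrix factorization that jointly learns
    continuous latent cellular contexts and context-specific eQTL effect sizes
    from paired expression and genotype data, fit by mean-field coordinate-ascent
    variational inference with automatic relevance determination priors.
    Includes the accompanying generative simulation framework, interaction-eQTL
    calling through linear mixed models with per-individual random intercepts,
    genotype-permutation empirical-FDR calibration, and construction of
    context-dependent squared eQTL effect-size annotations in LDSC .annot format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
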