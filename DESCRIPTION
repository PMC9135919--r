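Package: MetLipNet
Title: Covariate-Specific Metabolite-Lipid Association Networks
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers covariate-specific metabolite-lipid association networks
    from concentration profiles using the probabilistic context likelihood of
    relatedness on correlation (PCLRC), compares group-specific networks by
    node differential connectivity with a column-permutation null and
    Benjamini-Hochberg adjustment, and summarises large collections of
    networks by covariance simultaneous component analysis (COVSCA) with a
    t-SNE embedding of the scores. Includes covariate signal extraction by
    penalized regression, missForest-style random-forest imputation of
    clinical covariates, a seeded synthetic cohort generator with planted
    network rewiring for method validation, and an end-to-end reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    MASS,
    glmnet,
    ranger,
    pracma,
    igraph,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
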