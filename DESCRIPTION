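Package: medakasel
Title: Simulation and Bayesian Analysis of Bidirectional Size-Selection
    Experiments in Medaka
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pedigree-explicit simulation and Bayesian analysis of
    laboratory size-selection experiments on medaka (Oryzias latipes).
    Provides recursive pedigree kinship and inbreeding computation,
    sib-mating-aware pair assignment, inbreeding effective population size,
    a generative model of a multi-generation truncation-selection
    experiment (growth, maturation, survival, zero-inflated fecundity,
    egg traits, pituitary hormone expression, RT-qPCR quantification),
    a suite of hierarchical Bayesian trait models fitted by MCMC with
    Gelman-Rubin diagnostics, MCMC and posterior-predictive p-values,
    probabilistic maturation reaction norm (PMRN) estimation with full
    posterior propagation, Lande-Arnold style fitness regressions, and
    Bonferroni-corrected effect-size reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rjags,
    coda,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
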