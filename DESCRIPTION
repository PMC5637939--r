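Package: eqtlmap
Title: Sparse Bayesian Mapping of Multiple eQTLs from Paired Genotype and
    RNA-Seq Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simultaneous mapping of multiple gene/variant associations
    (expression quantitative trait loci, eQTLs) from a paired genotype
    dosage matrix and an RNA-seq count matrix. Four hierarchical regression
    models (Normal on transformed counts, over-dispersed Poisson,
    over-dispersed Binomial and Negative Binomial) share a three-level
    sparsity-inducing shrinkage prior with Jeffreys hyperpriors and are
    estimated by Gibbs sampling; the Negative Binomial and Binomial
    samplers use Polya-Gamma data augmentation. Includes a transformation
    suite for read counts (log, Box-Cox, Blom, Laplace smoothing followed
    by arcsin or logit), a template-style simulator of genotype/count/effect
    triplets, benchmarking metrics (Matthews correlation, RMSE among true
    positives, Lin's concordance correlation) and a Monte Carlo
    cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
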