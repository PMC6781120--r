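Package: ssrnm
Title: Single-Step Genomic Reaction Norm Models for Genotype-by-Environment
    Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying genotype-by-environment interaction in
    livestock populations with reaction norm models under single-step
    genomic BLUP. Builds pedigree (A), genomic (G) and combined (H)
    relationship matrices, estimates variance components by average
    information REML, samples group-wise heterogeneous residual variances
    with a Gibbs sampler, runs the three-step reaction norm procedure on
    herd effects as the environmental gradient, summarises G-by-E through
    variances, heritabilities and genetic correlations along the gradient,
    validates forward prediction against daughter yield deviations, and
    maps intercept and slope variation to SNP windows through an iterative
    weighted single-step GWAS. A synthetic-data generator with known truth
    makes the whole pipeline testable without access to proprietary cattle
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
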