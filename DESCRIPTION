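Package: egdelim
Title: Species Delimitation in Asexual Lineages with the K/theta Rule and
    the GMYC Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for delimiting evolutionary genetic (EG) species from
    single-locus alignments of asexual organisms. Implements the K/theta
    (4x) rule -- within-clade diversity theta, model-corrected
    between-clade divergence K, and the probability of reciprocal
    monophyly under a two-population coalescent -- and the generalized
    mixed Yule-coalescent (GMYC) model with single and multiple
    threshold fits, likelihood-ratio tests and +/-2 log-likelihood
    confidence sets. Includes neighbor-joining and UPGMA tree building
    with nonparametric bootstrap, maximum-likelihood pairwise distances
    under GTR-family models with invariant sites and discrete gamma rate
    variation, and a multispecies-coalescent simulator for generating
    benchmark data sets with known species boundaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
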