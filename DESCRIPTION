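Package: radsplit
Title: Marker Utility Analysis for Rapid-Radiation Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the phylogenetic utility of molecular markers
    across a rapid species radiation. Provides a multispecies-coalescent
    simulator with an optional introgression pulse (emulating a set of slow
    nuclear non-coding loci and one fast mitochondrial partition), sequence
    alignment input/output and concatenation, per-locus characterization
    (parsimony-informative sites, pairwise distances, numt-style coding
    integrity screens), maximum-likelihood inference under GTR-family models
    with discrete-gamma and invariant-site rate variation, Fitch parsimony and
    neighbor-joining with bootstrap and majority-rule consensus, AIC model
    selection, congruent-node scoring of per-gene trees against a reference
    tree, and Shimodaira-Hasegawa / Kishino-Hasegawa topology tests via RELL
    resampling.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
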