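Package: mitorescue
Title: Comparative Annotation and Molecular Evolution of Highly Divergent
    Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for re-annotating and re-analysing highly divergent plant
    mitochondrial genomes such as those of the mistletoe genus Viscum.
    Provides sensitive seed-and-extend nucleotide homology search with an
    exact Smith-Waterman oracle, HSP chaining into gene models and
    intact/truncated/pseudogene/absent classification with RNA-editing
    aware stop detection, Goldman-Yang codon-model maximum-likelihood
    dN/dS estimation (pairwise and branch-class) together with the
    Nei-Gojobori counting estimator, a branch-model selection-relaxation
    likelihood-ratio test, compensatory base-pair-change analysis of rRNA
    secondary structures, a GTR+Gamma likelihood engine with RELL-based
    KH/SH/AU topology tests and a phylogenetic screen for horizontally
    transferred genes, and a fully seeded synthetic mitogenome generator
    that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
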