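Package: recombMap
Title: LD-Based Recombination Maps and Their Downstream Effects on
    Haplotype Phasing and Genotype Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds windowed, linkage-disequilibrium-based recombination
    maps from phased haplotype panels and measures how the choice of map
    propagates into haplotype-phasing switch error and genotype-imputation
    concordance.  Provides a map-driven coalescent (ancestral recombination
    graph) simulator for reference panels and parent-offspring trios, a
    pairwise composite-likelihood estimator of the population-scaled
    recombination rate with a Monte-Carlo two-locus lookup, a sliding-window
    summary-statistic regression estimator, conversion between
    population-scaled rates and per-generation genetic maps, a Li & Stephens
    haplotype-copying HMM for phasing and imputation, and trio-based
    evaluation metrics (switch error rate, concordance by minor-allele
    frequency bin, Kruskal-Wallis group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    ranger
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
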