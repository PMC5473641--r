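Package: cladecons
Title: Detection and Dating of Clade-Specific Highly Conserved Genomic Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for finding genomic elements that are highly conserved
    within one clade of a species phylogeny but absent or fast-evolving in
    outgroups, in the style of the avian-specific highly conserved element
    (ASHCE) analyses used in comparative regulatory genomics. Provides
    reversible nucleotide substitution models with Felsenstein-pruning
    likelihoods, maximum-likelihood fitting of neutral models from
    fourfold-degenerate sites, a two-state phylogenetic hidden Markov model
    for conserved-element calling with log-odds scores, subtree-rate
    likelihood-ratio tests with FDR control for lineage-specific
    classification, genomic annotation and nearest-gene association,
    permutation-based interval enrichment, expression stage-specificity
    (tau) statistics, molecular-clock dating of conservation onset on a stem
    branch with bootstrap uncertainty, and forward simulators that generate
    every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    jsonlite,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
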