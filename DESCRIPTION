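Package: glompipe
Title: Barcode-Gap Evaluation and Amplicon Community Analysis for a
    Single-Copy Protein-Coding Marker
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate a single-copy protein-coding marker gene
    (such as RPB1 of the arbuscular mycorrhizal fungi) as a DNA barcode and
    to analyse amplicon-sequencing community data with it. Implements
    Kimura two-parameter distances with sliding-window and
    diagnostic-nucleotide profiles, barcode-gap analysis and OTU-threshold
    derivation; a pyrosequencing read-processing cascade (demultiplexing,
    length/ambiguity filtering, reference alignment screening, greedy
    preclustering, de novo two-parent chimera detection, and
    homopolymer frame-shift correction validated by stop-codon-free
    translation); greedy OTU clustering with three-way consensus taxonomy
    (k-mer naive Bayes classifier, parsimony placement on a reference tree,
    and bootstrapped neighbour-joining) and aggregation of OTUs into
    species-level molecular taxa; community statistics (rarefaction,
    unweighted and weighted UniFrac, principal coordinates analysis,
    ANOSIM); and a synthetic-data generator with per-read ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Matrix,
    phangorn,
    phytools,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    optparse,
    phyloseq,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
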