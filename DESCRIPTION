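Package: transitr
Title: Transitive siRNA Detection, Spreading Classification and
    Duplex-Energy Prediction for Small RNA Sequencing
Version: 0.9.0
Authors@R:
    person("transitr", "maintainers", email = "transitr@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for RDR6-dependent secondary (transitive)
    siRNA production from miRNA-targeted transcripts. Implements
    genome-wide size-stratified scanning-window read counting, a
    from-scratch exact negative-binomial two-group test with common
    dispersion, locus merging with miRNA-target enrichment (Fisher),
    cleavage-site-relative siRNA profiling with 5'/3'/bidirectional
    spreading classification, nearest-neighbor RNA-RNA hybridization
    free-energy prediction of the spreading side with exact binomial
    significance, and classification of non-templated 3' tails in
    3'-RACE clones. A deterministic synthetic-data generator (genome,
    annotation, target sites, alignments across genotypes and
    replicates, RACE clones, with machine-readable ground truth) makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    BiocGenerics,
    GenomicRanges,
    rtracklayer
Suggests:
    Rsamtools,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
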