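Package: pirdisco
Title: Identification and Characterization of Putative piRNAs from Small RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for discovering and characterizing
    putative PIWI-interacting RNAs (piRNAs) in aligned small RNA-seq data
    across a differentiation time course. Implements the read-length and
    strand-specific ncRNA filtering cascade, locus-level quantification and
    expressed-set calling, negative-binomial differential expression with
    median-of-ratios normalization, fuzzy c-means soft clustering of
    temporal expression trajectories, biogenesis-signature statistics
    (per-position base composition / 5' uridine bias, ping-pong 10-nt
    5'-5' overlap z-score, locus coverage meta-profiles), and genomic
    context analyses (host-gene assignment, interval-shuffling enrichment
    null, host-gene percent coverage, piRNAs-per-gene tallies, and
    hypergeometric gene-set overrepresentation). Ships a synthetic-data
    generator with planted ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    e1071,
    knitr
Config/testthat/edition: 3
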