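Package: nucoccupancy
Title: Intrinsic Nucleosome Occupancy at Regulatory Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores DNA sequence for intrinsic (DNA-encoded) nucleosome
    occupancy with a trainable position-specific dinucleotide energy model
    and a thermodynamic dynamic program with hard-core exclusion, normalizes
    per-base genome tracks on a log2 scale around the genomic mean, builds
    promoter and CpG-island region sets, computes strand-aware meta-profiles
    and 150-bp windowed sequence statistics (G+C, poly-A), and relates
    intrinsic occupancy to (simulated) in vivo nucleosome coverage via
    base-by-base correlation, spacing-constrained subsampling, and quadrant
    fractions. Includes a synthetic-genome and MNase-style coverage
    simulator with known ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tools,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
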