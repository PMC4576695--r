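Package: fourc
Title: Analysis of 4C Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of circularized chromosome conformation
    capture (4C) sequencing experiments. Builds a restriction-fragment
    reference by in-silico digestion of a genome, counts protocol-valid
    aligned reads onto fragment ends, applies a variance-stabilizing
    transformation for negative-binomial counts, fits a smooth monotone
    decay of signal with genomic distance from the viewpoint, calls
    specific viewpoint interactions from MAD-scaled z-scores with FDR
    control, and tests for differential contacts between conditions with
    a negative-binomial GLM Wald test using fit-derived normalization
    factors. Includes a synthetic-data generator producing toy genomes,
    protocol-conforming alignments and count matrices with known truth
    for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    graphics,
    methods,
    pracma,
    splines,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    GenomeInfoDb,
    GenomicRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
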