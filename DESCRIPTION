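Package: orgcn
Title: Organelle Genome Copy Number Estimation from Sequencing Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome-sequencing based estimation of organelle genome copy
    number per cell, with plastid-read exclusion, 500-bp windowed CPM coverage
    relative to a reference sample, coverage-based deletion calling, SNP-based
    disambiguation of mitochondrial reads from nuclear-mitochondrial insertions
    (NUMTs), qPCR delta-Ct relative quantification, genome-stratified
    differential-expression proportion statistics with Fisher exact contrasts,
    and copy-number-expression association. Ships a synthetic multi-compartment
    cell forge (reference genomes, mutant derivatives, labelled paired-end
    reads, qPCR Ct tables, RNA-seq count matrices) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    limma,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
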