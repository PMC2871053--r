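Package: srnaloc
Title: Nuclear and Cytoplasmic Small RNA Sequencing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired nuclear and cytoplasmic small-RNA
    deep-sequencing libraries. Cleans and collapses 16-30 nt reads, maps them
    to a genome by exact all-occurrence matching with rescue stages for rRNA
    units, splice junctions, CCA-tailed tRNAs, single-mismatch tRNA reads and
    3' untemplated additions, assigns each sequence one RNA class through an
    ordered annotation cascade, calls tRNA 3' trailer small RNAs from the 40 nt
    downstream of tRNA genes, groups isomiRs, normalizes to reads per million,
    and computes nuclear/cytoplasmic (N/C) enrichment statistics. Includes a
    seeded synthetic-data generator with full ground truth for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
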