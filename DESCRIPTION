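Package: checOrigins
Title: Genome-Wide Mapping of Candidate Replication Origins from MCM-ChEC
    Fragment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies and characterizes candidate Mcm helicase binding
    sites (CMBSs) in budding yeast from chromatin endogenous cleavage
    (ChEC) paired-end fragment data.  Provides size-selected per-base
    coverage and fragment-midpoint tracks, an iterative dual-track peak
    caller with exclusion zones and annotation-based filtering,
    anchor-aligned composite and heatmap matrices, nucleosome-free-region
    scoring, genic/intergenic and flanking-gene-orientation annotation,
    ARS-consensus-sequence position-weight-matrix scanning, strand-resolved
    GC-skew profiling, origin-licensing regression, and a seeded
    synthetic-data generator that emulates every input so the full
    pipeline can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
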