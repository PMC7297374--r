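Package: pafinder
Title: Poly(A) Tail Length Profiling from Direct Tail Sequencing Reads
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls poly(A) tail lengths per read and per gene from
    Illumina-style reads that run 5' to 3' through the 3'UTR into the
    homopolymeric tail. Detects the tail with fuzzy 9-A/6-A anchor scans,
    refines it by splitting on long non-A runs and requiring a pure
    adenosine core, optionally truncates instrument signal bleeding with a
    Phred-quality sliding-window filter, and scans for the 3' adaptor
    downstream of the tail. Includes a toy ungapped anchor mapper and
    SAM/BAM import for gene assignment, per-gene median tail statistics
    and figure-ready composition tables, spike-in read retrieval, and a
    synthetic read simulator with a junction quality-collapse and
    A-signal-bleeding noise model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
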