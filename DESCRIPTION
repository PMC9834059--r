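Package: tailcapR
Title: PolyA Tail Profiling from End-Capture Nanopore cDNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing template-switching (end-capture) nanopore cDNA
    sequencing of RNA 3' ends. Estimates per-read polyA tail lengths from raw
    current signal by locating the low-variance tail segment and converting its
    duration to nucleotides with a per-read translocation rate; extracts
    base-called tails from soft-clipped alignment bases and classifies their
    nucleotide composition (terminal and internal non-A additions); filters
    incomplete reads and assigns reads to transcript isoforms by 3' end
    agreement with annotation; summarises tail lengths per gene and isoform
    with Kruskal-Wallis/Benjamini-Hochberg divergence scans; and profiles
    per-site mismatch and drop-off rates to detect RNA modifications. A
    squiggle and alignment simulator with known ground truth, including the
    published synthetic cDNA tail standards, makes every stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
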