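Package: methylsplice
Title: Integrative Analysis of Tissue-Specific DNA Methylation and
    Alternative Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls tissue-specific differentially methylated regions
    (T-DMRs) from two-channel tiling-array intensities, detects
    alternatively spliced exons from exon-level expression via the
    splicing index, classifies methylation-to-splicing regulation as
    positive or negative, and discovers position-dependent 6mer motifs
    enriched in T-DMRs flanking alternatively spliced exons, with
    CpG-content, conservation and motif-spacing statistics. Includes a
    synthetic-data generator that plants T-DMRs, spliced exons,
    regulatory couplings and motifs so every stage of the pipeline can
    be benchmarked against a known truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    limma,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
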