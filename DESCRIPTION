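Package: aluex
Title: Detection of Alu Exonization Events from RNA-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects incorporation of Alu element sequences into mRNA
    transcripts from short-read RNA-seq. One arm calls and characterizes
    exonization events at Alu elements present in the reference genome from
    assembled transcript models (antisense/internal/length filters,
    cross-sample merging, intron-support rescue, cassette-exon detection and
    percent-spliced-in quantification, tissue-specificity testing). The other
    arm predicts non-reference (polymorphic) Alu insertions in genes from
    non-concordant read pairs, using a k-mer Alu read classifier, a spliced
    signal/shadow alignment test, category clustering with context filters,
    insertion-interval inference, and de Bruijn contig assembly with
    genomic-match prioritization. A seedable synthetic-data generator and an
    excision-based calibration protocol make the full pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
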