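Package: FusionScope
Title: Harmonization, Filtering and Functional Annotation of Long-Read
    Gene Fusion Calls in Glioma Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-caller analysis of ensemble gene-fusion calls from
    long-read (Oxford Nanopore) whole-transcriptome sequencing of glioma.
    Normalizes and deduplicates multi-caller fusion calls with breakpoint
    windows and reciprocal collapse, applies a multistep filtering cascade
    with a per-stage audit trail, classifies breakpoints against a
    three-tiered transcript model (MANE Select, longest protein-coding,
    all transcripts) with near-exon reclassification, prioritizes fusion
    partner genes against cancer and glioma gene resources including
    essentiality-screen summaries, relates fusion breakpoints to
    transcript-isoform structures (novel-isoform clustering, consensus
    differential expression, breakpoint-proximal boundary detection), and
    assembles breakpoint-defined chimeric cDNA constructs with open
    reading frame and junction-microhomology analysis. A seeded synthetic
    data generator produces annotation, sequence, fusion-call and isoform
    fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneFusionDetection, Annotation, Sequencing,
    LongRead
RoxygenNote: 7.3.3
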