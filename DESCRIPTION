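Package: chemclipseq
Title: Enrichment Analysis for Chemical Cross-Linking Pull-Down Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies transcripts selectively bound by a small molecule from
    Chem-CLIP-Seq coverage tracks. Computes per-nucleotide pull-down/input
    enrichment ratios, fits a log-normal null model, compiles significant
    nucleotides into candidate regions, applies a four-stage filter cascade
    (area under curve, region length, read count, replicate-consistent fold
    enrichment), aggregates regions to transcript-level per-million-normalized
    enrichment, quantifies enrichment in a fixed window around a repeat locus,
    and classifies treatment rescue of dysregulated expression and splicing.
    Includes a synthetic-data generator with known ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, Coverage, PeakDetection, Transcriptomics, Software
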