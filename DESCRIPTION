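Package: isotarget
Title: Isoform-Specific Transcription Factor Target Analysis from
    Knockout ChIP-seq and RNA-seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates pan-factor ChIP-seq peak calls from wild-type and
    two isoform-specific knockout genotypes with knockout RNA-seq to
    classify binding sites by isoform ownership, call direct target genes,
    and screen peak-centered windows for differentially abundant
    transcription factor motifs. Includes interval algebra over peak sets,
    a transparent negative-binomial Wald test with median-of-ratios
    normalization, hypergeometric over-representation and GSEA-style
    enrichment statistics, exact dynamic-programming PWM score thresholds,
    and a synthetic-data generator that plants ownership labels, expression
    effects, motif instances and enriched gene sets with recoverable ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    DESeq2,
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ChIPSeq, RNASeq, DifferentialExpression, MotifAnnotation,
    GeneSetEnrichment, Software
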