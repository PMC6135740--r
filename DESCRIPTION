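Package: lineageseq
Title: Lineage-Resolved Analysis of Cleavage-Stage Embryo Single-Cell RNA-seq
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis workflow for single-cell RNA-seq of mouse preimplantation
    embryos in which the two blastomeres of the 2-cell embryo are heritably
    labelled with Brainbow fluorescent markers. Assigns each blastomere to a
    cell-division lineage from marker-mapped read counts, classifies
    blastocysts as balanced or unbalanced in lineage contribution to the
    embryonic and abembryonic poles from imaging counts, detects
    transcriptome-wide between-lineage expression differences with a nested
    ANOVA variance-partition ratio compared against Beta distributions and a
    shuffled-label q-value background, and calls transposon-related novel
    transcript isoforms (TRENIs) with junction-read support and repeat-family
    enrichment odds ratios. A synthetic-data generator emulates every input so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomicAlignments,
    Rsamtools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
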