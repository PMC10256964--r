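Package: emats
Title: Identification of EMATS Genes and Splicing-Transcription Coupling
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies human genes with an EMATS architecture (exon-mediated
    activation of transcription starts): a weak alternative first exon located
    within 5 kb upstream of a strongly included skipped exon. Builds
    strand-aware meta-exons from GTF annotation, classifies exons from splice
    junction read imbalance, quantifies first-exon usage and exon-skipping
    percent-spliced-in (PSI) from junction counts, applies the three EMATS
    criteria per tissue and across tissues, annotates pathogenic variants by
    positional zone relative to EMATS exons, and quantifies the coupling
    between exon inclusion and host-gene expression with Spearman statistics.
    Ships a synthetic-data generator with planted ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
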