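Package: dualscreen
Title: Integration of High-Content and Transcriptome siRNA Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to identify functional interactions between chromatin
    regulators from paired siRNA screens during iPSC reprogramming:
    per-plate Z-score normalization of high-content feature tables and
    knockdown phenotype correlation, a simple differential-expression
    substitute on log2-CPM with Benjamini-Hochberg adjustment,
    dual-evidence correlation networks, hypergeometric gene-set overlap
    enrichment and three-set venn decomposition, log2 fold-change
    clustering and max-normalized trajectory summaries, and
    promoter/peak/coverage integration (peak-to-gene assignment,
    RPM/RPKM region signal, summit-centered signal matrices). A
    synthetic-data module generates every input with known ground truth
    so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
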