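Package: uptf
Title: Upstream Transcription Factor Enrichment Analysis for Plant Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies transcription factors (TFs) whose empirically
    determined target genes (from DAP-seq or ChIP-seq cistrome databases)
    are over-represented in a user-supplied list of genes of interest.
    Over-representation is assessed with upper-tail hypergeometric or
    binomial tests against an explicit background universe, corrected for
    multiple testing by Benjamini-Hochberg or Bonferroni procedures, and
    reported as ranked tables. Also builds TF-target databases from peak
    BED files plus a GFF3 gene annotation using a strand-aware
    promoter-plus-gene-body assignment rule, and exports TF-target
    regulatory networks in Cytoscape-loadable SIF format with per-node
    degree and neighborhood-connectivity attributes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    optparse,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
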