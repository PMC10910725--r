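Package: coexnet
Title: Gene Co-Expression Network Analysis with PCIT, Regulatory Impact
    Factors and MCODE-Style Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end workflow for across-condition gene co-expression
    network analysis of bulk RNA-seq experiments with factorial designs
    (tissue x breed x phenotype group x diet phase). Provides CPM/TMM
    expression preparation and per-contrast negative-binomial differential
    expression via edgeR with top-fraction gene selection; regulatory impact
    factor (RIF1/RIF2) scoring of transcription factors against
    differentially expressed targets; partial-correlation and information
    theory (PCIT) network inference with dual significance thresholds;
    MCODE-style k-core clustering of the resulting network; and hub,
    first-neighbour and cross-contrast overlap summaries. A negative-binomial
    count simulator with planted differential expression, latent
    co-expression modules and a differentially wired regulator makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    edgeR,
    fgsea,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
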