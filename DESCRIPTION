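Package: circmeth
Title: Integrative circRNA Expression and DNA Methylation Analysis with
    Simulated Multi-Omics Ground Truth
Version: 0.1.0
Authors@R:
    person("circmeth", "Maintainers", email = "circmeth@example.org",
           role = c("aut", "cre"))
Description: Tools for the integrative analysis of circular RNA (circRNA)
    expression and DNA methylation in paired tumor/normal designs:
    negative-binomial differential expression for gene, circRNA
    back-splice-junction and miRNA count matrices; beta-to-M moderated-t
    differential methylation; construction of circRNA-relative flanking
    regions (Pre2000/Interior/After2000) and probe-to-region mapping;
    identification of differentially expressed circRNAs harboring
    differentially methylated sites whose parental genes are not
    differentially expressed; Spearman methylation-expression correlation;
    direction-constrained circRNA-miRNA-mRNA (ceRNA) network assembly with
    seed matching and a simplified duplex score; a cross-validated ROC/AUC
    classification harness; and a synthetic paired multi-omics simulator
    with a planted, manifest-recorded ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    igraph,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
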