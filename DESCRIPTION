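Package: microdevnet
Title: Developmental Microglia Transcriptomics and Tissue-Context
    Functional Gene Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for developmental microglia RNA-seq
    contrasts across four stages (yolk sac, brain rudiment, neonate,
    adult) in wild-type versus knock-in genotypes: counts-per-million
    normalization and a log-based variance-stabilizing transform, a
    self-contained common-dispersion negative-binomial exact test with
    Benjamini-Hochberg FDR control, parametric gene-set enrichment
    (PAGE) for GO-like sets and transcription-factor regulons, a
    distance-based permutation separation test with Phipson-Smyth
    p-values (with gene-subsampling robustness and a signature-gene
    variant), classical multidimensional scaling and signature-restricted
    PCA, and a tissue-context naive-Bayes functional gene network with
    gold-standard construction, cross-validation, seed-gene neighborhood
    and transcription-factor linking queries. A synthetic-data module
    generates negative-binomial counts, gene sets, pairwise evidence
    datasets and ortholog maps with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
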