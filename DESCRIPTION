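Package: angiocol
Title: Collagen-Linked Angiogenesis Analysis of the Tumor Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking intratumoral collagen to angiogenesis across
    bulk, single-cell and spatial transcriptomics. Provides single-sample
    gene-set enrichment (ssGSEA running-sum) scoring, reference-based
    endothelial deconvolution, a six-feature composite angiogenesis score,
    immuno-collagenic subtyping (quiescent, armored & cold, soft & hot) from
    transcriptomic or histology scores, Welch-t differential expression with
    fold-change gating, preranked gene-set enrichment with a set-permutation
    null, single-cell QC/reduction/annotation and a ligand-receptor
    label-permutation interaction test, nearest-cell-type spatial proximity
    statistics, Kaplan-Meier/log-rank survival evaluation, and seeded
    synthetic-data generators with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    survival,
    utils,
    yaml
Suggests:
    fgsea,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
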