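Package: riskConverge
Title: Convergence of Disease Risk Genes on Amyloid-Responsive Microglial
    Co-Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable, tested implementation of an integrative
    transcriptomics pipeline linking polygenic disease risk to an
    amyloid-responsive, microglia-dominated gene program. The package fits
    2x2 age-by-genotype interaction models to bulk RNA-seq counts, tests
    nested GWAS risk-gene sets for enrichment in signed rankings with a
    weighted running-sum statistic and gene-set resampling null, builds
    unsigned co-expression modules via topological overlap, computes an
    exact multi-set intersection test, quantifies cell-type composition
    shifts with a baseline-anchored z-score statistic and resampling null,
    classifies single-cell microglia into homeostatic and activated states,
    and regresses observed bulk expression on a microgliosis-aware
    prediction from single-cell state means. A synthetic-data module
    generates bulk, GWAS-table, marker-set and single-cell inputs with
    known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    limma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bulkDE.R'
    'coexpression.R'
    'deconvolution.R'
    'utils.R'
    'enrichment.R'
    'intersection.R'
    'singleCell.R'
    'shift.R'
    'simulate.R'
    'pipeline.R'
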