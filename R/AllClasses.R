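#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData rowData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' BulkExperiment: bulk RNA-seq counts with a 2x2 factorial sample design
#'
#' A thin subclass of [SummarizedExperiment::SummarizedExperiment] holding a
#' gene-by-sample matrix of raw read counts (assay `"counts"`) together with
#' the per-sample design of a two-strain, age-by-genotype study: `strain`
#' (e.g. an amyloid and a tau model), `age` (4M/10M), `genotype` (WT/TG),
#' plus the technical covariates `batch` and `concentration` used for
#' nuisance-variable removal.
#'
#' Validity requires non-negative integral counts, the design columns to be
#' present, and - for every strain present in the object - all four
#' age-by-genotype cells to contain at least two samples, so that per-group
#' means and residual variances are estimable.
#'
#' @slot .Data see [SummarizedExperiment::SummarizedExperiment]
#' @seealso [BulkExperiment()] for the constructor
#' @export
setClass("BulkExperiment", contains = "SummarizedExperiment")

.validBulkExperiment <- function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(cts - round(cts)) > 1e-8))
      msg <- c(msg, "counts must be integral")
  }
  cd <- colData(object)
  needed <- c("strain", "age", "genotype")
  missing <- setdiff(needed, colnames(cd))
  if (length(missing))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missing, collapse = ", ")))
  if (!length(missing) && ncol(object) > 0) {
    for (st in unique(cd$strain)) {
      sub <- cd[cd$strain == st, , drop = FALSE]
      tab <- table(sub$age, sub$genotype)
      if (any(dim(tab) < 2) || any(tab < 2))
        msg <- c(msg, paste0("strain ", st, ": every age x genotype cell ",
                             "needs >= 2 samples"))
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("BulkExperiment", .validBulkExperiment)

#' Construct a BulkExperiment
#'
#' @param counts gene-by-sample matrix of non-negative integer raw counts;
#'   rownames are gene ids, colnames sample ids.
#' @param samples `data.frame`/`DataFrame` with one row per sample and at
#'   least columns `strain`, `age`, `genotype`; technical covariates such as
#'   `batch` and `concentration` may be included.
#' @return a [BulkExperiment-class] object.
#' @examples
#' cts <- matrix(rpois(40 * 16, 50), 40, 16,
#'               dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:16)))
#' sam <- data.frame(strain = "APP",
#'                   age = rep(c("4M", "10M"), each = 8),
#'                   genotype = rep(c("WT", "TG"), times = 8))
#' be <- BulkExperiment(cts, sam)
#' be
#' @export
BulkExperiment <- function(counts, samples) {
  counts <- as.matrix(counts)
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = DataFrame(samples))
  new("BulkExperiment", se)
}

#' CellExperiment: single-cell UMI counts with group labels and QC metrics
#'
#' Subclass of [SingleCellExperiment::SingleCellExperiment] with assay
#' `"counts"` (gene-by-cell UMIs) and per-cell columns `group` (experimental
#' group, strain x age x genotype), `total` (total UMI count) and `mitoFrac`
#' (fraction of counts on mitochondrial genes). The mitochondrial gene set
#' is recorded in `metadata(x)$mitoGenes`; validity recomputes `mitoFrac`
#' from the matrix and requires agreement to 1e-9.
#'
#' @seealso [CellExperiment()]
#' @export
setClass("CellExperiment", contains = "SingleCellExperiment")

.validCellExperiment <- function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  cd <- colData(object)
  needed <- c("group", "total", "mitoFrac")
  missing <- setdiff(needed, colnames(cd))
  if (length(missing))
    return(paste0("colData lacks column(s): ", paste(missing, collapse = ", ")))
  cts <- assay(object, "counts")
  tot <- Matrix::colSums(cts)
  if (any(abs(tot - cd$total) > 1e-6))
    msg <- c(msg, "colData$total must equal column sums of counts")
  if (any(cd$mitoFrac < 0 | cd$mitoFrac > 1))
    msg <- c(msg, "mitoFrac must lie in [0, 1]")
  mito <- intersect(metadata(object)$mitoGenes, rownames(object))
  mtot <- if (length(mito)) Matrix::colSums(cts[mito, , drop = FALSE]) else 0
  frac <- ifelse(tot > 0, mtot / tot, 0)
  if (any(abs(frac - cd$mitoFrac) > 1e-9))
    msg <- c(msg, "mitoFrac must equal mito-gene counts / total counts")
  if (length(msg)) msg else TRUE
}
setValidity("CellExperiment", .validCellExperiment)

#' Construct a CellExperiment
#'
#' @param counts gene-by-cell matrix (dense or `dgCMatrix`) of UMI counts.
#' @param groups character/factor of per-cell experimental group labels.
#' @param mitoGenes character vector of mitochondrial gene ids (subset of
#'   rownames).
#' @param trueState optional per-cell ground-truth state labels (synthetic
#'   data only); stored in `colData`.
#' @return a [CellExperiment-class] object with `total` and `mitoFrac`
#'   computed from the matrix.
#' @export
CellExperiment <- function(counts, groups, mitoGenes = character(),
                           trueState = NULL) {
  total <- Matrix::colSums(counts)
  mito <- intersect(mitoGenes, rownames(counts))
  mtot <- if (length(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else
    rep(0, ncol(counts))
  cd <- DataFrame(group = as.character(groups), total = as.numeric(total),
                  mitoFrac = ifelse(total > 0, mtot / total, 0),
                  row.names = colnames(counts))
  if (!is.null(trueState)) cd$trueState <- as.character(trueState)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  metadata(sce)$mitoGenes <- mito
  new("CellExperiment", sce)
}

#' GroundTruth: latent parameters behind a synthetic dataset
#'
#' Captures everything the synthetic-data generators decided, so that
#' downstream estimates can be scored against truth: which genes carry a
#' real interaction effect and how large (log2 units), which genes are
#' "risk" genes and their assigned association p-values, the planted
#' program/module membership, the per-group cell-state composition, and the
#' per-group relative microglial abundance (microgliosis, baseline 1).
#'
#' @slot deGenes character; genes with a true nonzero interaction effect.
#' @slot interactionLfc named numeric; true log2 interaction effect per gene.
#' @slot riskGenes named numeric; true association p-value per risk gene.
#' @slot moduleAssignment named character; true program label per gene.
#' @slot stateFractions numeric matrix, group x state, rows summing to 1.
#' @slot microgliosisFactor named numeric >= 1 per group.
#' @slot seed integer seed the generator ran under.
#' @export
setClass("GroundTruth",
  representation(deGenes = "character", interactionLfc = "numeric",
                 riskGenes = "numeric", moduleAssignment = "character",
                 stateFractions = "matrix", microgliosisFactor = "numeric",
                 seed = "integer"))

.validGroundTruth <- function(object) {
  msg <- character()
  sf <- object@stateFractions
  if (length(sf) && nrow(sf)) {
    if (any(abs(rowSums(sf) - 1) > 1e-12))
      msg <- c(msg, "stateFractions rows must sum to 1 (tol 1e-12)")
    if (any(sf < 0)) msg <- c(msg, "stateFractions must be non-negative")
  }
  mf <- object@microgliosisFactor
  if (length(mf) && any(mf < 1 - 1e-12))
    msg <- c(msg, "microgliosisFactor must be >= 1")
  lfc <- object@interactionLfc
  if (length(lfc) && !all(object@deGenes %in% names(lfc)[lfc != 0]))
    msg <- c(msg, "deGenes must be the genes with nonzero interactionLfc")
  if (length(msg)) msg else TRUE
}
setValidity("GroundTruth", .validGroundTruth)

GroundTruth <- function(deGenes = character(), interactionLfc = numeric(),
                        riskGenes = numeric(), moduleAssignment = character(),
                        stateFractions = matrix(numeric(), 0, 0),
                        microgliosisFactor = numeric(), seed = NA_integer_) {
  new("GroundTruth", deGenes = deGenes, interactionLfc = interactionLfc,
      riskGenes = riskGenes, moduleAssignment = moduleAssignment,
      stateFractions = stateFractions,
      microgliosisFactor = microgliosisFactor, seed = as.integer(seed))
}

#' ModulePartition: co-expression modules with eigengenes and TOM
#'
#' Result container of module detection: a gene-to-module labelling (the
#' reserved label `"unassigned"` collects leftovers), per-module eigengene
#' profiles across samples (first principal component scores), and the
#' topological overlap matrix the clustering ran on.
#'
#' @slot labels named character, gene -> module.
#' @slot eigengenes numeric matrix, module x sample.
#' @slot tom symmetric numeric matrix in `[0,1]` with unit diagonal.
#' @slot fitTable data.frame from soft-power selection (may be empty).
#' @export
setClass("ModulePartition",
  representation(labels = "character", eigengenes = "matrix",
                 tom = "matrix", fitTable = "data.frame"))

.validModulePartition <- function(object) {
  msg <- character()
  tom <- object@tom
  if (length(tom)) {
    if (nrow(tom) != ncol(tom) || max(abs(tom - t(tom))) > 1e-8)
      msg <- c(msg, "tom must be symmetric")
    if (any(tom < -1e-8) || any(tom > 1 + 1e-8))
      msg <- c(msg, "tom entries must lie in [0, 1]")
    if (max(abs(diag(tom) - 1)) > 1e-8)
      msg <- c(msg, "tom diagonal must be 1")
  }
  mods <- setdiff(unique(object@labels), "unassigned")
  if (length(object@eigengenes) && nrow(object@eigengenes) &&
      !all(rownames(object@eigengenes) %in% c(mods, "unassigned")))
    msg <- c(msg, "eigengene rows must correspond to module labels")
  if (length(msg)) msg else TRUE
}
setValidity("ModulePartition", .validModulePartition)

#' IntersectionTest: exact multi-set intersection statistic
#'
#' The exact null distribution of the size of the intersection of k sets of
#' fixed sizes drawn uniformly and independently from a background of N
#' genes, together with the observed overlap, its expectation
#' N * prod(n_i / N), and the upper-tail p-value P(X >= observed).
#'
#' @slot backgroundSize integer N.
#' @slot setSizes integer vector n_1..n_k.
#' @slot observed integer observed overlap.
#' @slot expected numeric expectation in genes.
#' @slot pUpper numeric upper-tail p-value.
#' @slot distribution named numeric; P(X = x) for x = 0..min(n_i).
#' @export
setClass("IntersectionTest",
  representation(backgroundSize = "integer", setSizes = "integer",
                 observed = "integer", expected = "numeric",
                 pUpper = "numeric", distribution = "numeric"))

.validIntersectionTest <- function(object) {
  msg <- character()
  d <- object@distribution
  if (abs(sum(d) - 1) > 1e-12)
    msg <- c(msg, "distribution must sum to 1 (tol 1e-12)")
  ev <- sum(as.numeric(names(d)) * d)
  if (abs(ev - object@expected) > 1e-9)
    msg <- c(msg, "expected must equal the distribution mean (tol 1e-9)")
  lo <- max(0, sum(object@setSizes) - (length(object@setSizes) - 1) *
              object@backgroundSize)
  hi <- min(object@setSizes)
  x <- as.numeric(names(d))
  if (any(d > 1e-15 & (x < lo | x > hi)))
    msg <- c(msg, "distribution support outside feasible overlap bounds")
  if (length(msg)) msg else TRUE
}
setValidity("IntersectionTest", .validIntersectionTest)
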