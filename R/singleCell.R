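#' @include AllClasses.R utils.R
NULL

#' Quality-control filtering of single-cell data
#'
#' Removes cells with fewer than `minReads` total counts, more than
#' `maxMito` mitochondrial fraction, or more than `doubletCap` total counts
#' (doublet rule), in that order of precedence for the recorded failure
#' reason; then removes genes detected in fewer than `minCellsPerGene` of
#' the surviving cells. The doublet cap is applied to total counts: the
#' classic "30,000 genes" phrasing cannot be literal for a sub-30,000-gene
#' transcriptome and is read as counts here (the unit stays configurable
#' through the threshold itself).
#'
#' @param ce a [CellExperiment-class].
#' @param minReads minimum total counts per cell (default 750).
#' @param maxMito maximum mitochondrial fraction (default 0.05).
#' @param doubletCap maximum total counts per cell (default 30000).
#' @param minCellsPerGene minimum number of surviving cells a gene must be
#'   detected in (default 100).
#' @return list with `experiment` (filtered [CellExperiment-class]),
#'   `cellReport` (DataFrame: barcode, total, mitoFrac, pass, reason) and
#'   `geneReport` (DataFrame: gene, nCellsDetected, retained).
#' @export
qcFilter <- function(ce, minReads = 750, maxMito = 0.05,
                     doubletCap = 30000, minCellsPerGene = 100) {
  stopifnot(minReads >= 0, maxMito >= 0, doubletCap > 0,
            minCellsPerGene >= 0)
  cd <- colData(ce)
  reason <- rep(NA_character_, ncol(ce))
  reason[cd$total < minReads] <- "low_reads"
  reason[is.na(reason) & cd$mitoFrac > maxMito] <- "high_mito"
  reason[is.na(reason) & cd$total > doubletCap] <- "doublet_cap"
  pass <- is.na(reason)
  if (!any(pass)) stop("no cells survive QC")
  cellReport <- DataFrame(barcode = colnames(ce),
                          total = cd$total, mitoFrac = cd$mitoFrac,
                          pass = pass, reason = reason)
  kept <- ce[, pass]
  det <- Matrix::rowSums(assay(kept, "counts") > 0)
  retained <- det >= minCellsPerGene
  geneReport <- DataFrame(gene = rownames(ce),
                          nCellsDetected = as.integer(det),
                          retained = retained)
  out <- kept[retained, ]
  list(experiment = out, cellReport = cellReport, geneReport = geneReport)
}

#' Library-size log-normalization of single-cell counts
#'
#' `value = ln(1 + scale * umi / cellTotal)` with the cell total taken from
#' the current matrix; stored as assay `"logcounts"`. Scale-invariant:
#' multiplying a cell's counts by a constant leaves its values unchanged.
#'
#' @param ce a [CellExperiment-class] (post-QC).
#' @param scale scaling constant (default 1e4).
#' @return `ce` with a `"logcounts"` assay added.
#' @export
normalizeCells <- function(ce, scale = 1e4) {
  cts <- assay(ce, "counts")
  tot <- Matrix::colSums(cts)
  if (any(tot == 0)) stop("zero-total cell(s) present; run qcFilter first")
  if (methods::is(cts, "sparseMatrix")) {
    norm <- as(cts %*% Matrix::Diagonal(x = scale / tot), "CsparseMatrix")
    norm@x <- log1p(norm@x)
    dimnames(norm) <- dimnames(cts)
  } else {
    norm <- log1p(t(t(cts) * (scale / tot)))
  }
  SummarizedExperiment::assay(ce, "logcounts") <- norm
  ce
}

#' Expression-bin-matched module score per cell
#'
#' For each marker gene, control genes are drawn from the gene's
#' average-expression bin (`nBins` equal-count bins over all genes by mean
#' normalized expression), excluding the marker set itself so the contrast
#' is against background genes of matched abundance; the score is the
#' per-cell mean expression over
#' marker genes minus the mean over the aggregated control draws - the
#' classic bin-matched signature score. Empty bins fall back to the nearest
#' non-empty bin with a warning.
#'
#' @param ce a [CellExperiment-class] with `"logcounts"`.
#' @param markerSet character marker gene set (intersected with rownames).
#' @param nBins number of average-expression bins (default 24).
#' @param nCtrlPerGene control genes drawn per marker gene (default 100).
#' @param seed integer seed for the control draws.
#' @return numeric per-cell score vector.
#' @export
moduleScore <- function(ce, markerSet, nBins = 24, nCtrlPerGene = 100,
                        seed = 1) {
  x <- assay(ce, "logcounts")
  set <- intersect(markerSet, rownames(x))
  if (!length(set)) stop("marker set has no member in the matrix")
  avg <- Matrix::rowMeans(x)
  nBins <- min(nBins, max(1L, length(unique(avg)) - 1L))
  br <- unique(stats::quantile(avg, probs = seq(0, 1,
                                                length.out = nBins + 1)))
  bin <- as.integer(cut(avg, breaks = br, include.lowest = TRUE))
  names(bin) <- rownames(x)
  byBin <- split(rownames(x), bin)

  byBin <- lapply(byBin, setdiff, set)  # controls never include the set
  ctrl <- .withSeed(.subSeed(seed, "moduleScoreCtrl"), {
    unlist(lapply(set, function(g) {
      b <- bin[g]
      pool <- byBin[[as.character(b)]]
      if (is.null(pool) || !length(pool)) {
        warning("empty expression bin; using nearest non-empty bin")
        avail <- as.integer(names(byBin))
        pool <- byBin[[as.character(avail[which.min(abs(avail - b))])]]
      }
      sample(pool, nCtrlPerGene, replace = length(pool) < nCtrlPerGene)
    }))
  })
  setMean <- Matrix::colMeans(x[set, , drop = FALSE])
  ctrlMean <- Matrix::colMeans(x[ctrl, , drop = FALSE])
  as.numeric(setMean - ctrlMean)
}

#' Assign each cell to the state with the highest signature score
#'
#' Cells are labelled by the argmax of their per-state module scores, ties
#' broken lexicographically; per-group state fractions are computed over
#' the assigned cells. A homeostatic signature must be among the states.
#'
#' @param scores cell-by-state numeric matrix of module scores (e.g.
#'   columns built with [moduleScore()]).
#' @param groups per-cell group labels (same length as rows of `scores`).
#' @param homeostatic name of the homeostatic state column.
#' @return list with `states` (per-cell label), `fractions` (group-by-state
#'   matrix, rows summing to 1) and `scores`.
#' @export
assignStates <- function(scores, groups, homeostatic = "HM") {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stop("need >= 2 state signatures")
  if (!homeostatic %in% colnames(scores))
    stop("missing homeostatic signature '", homeostatic, "'")
  ord <- order(colnames(scores))
  s <- scores[, ord, drop = FALSE]
  lab <- colnames(s)[max.col(s, ties.method = "first")]
  tab <- table(factor(groups), factor(lab, levels = sort(colnames(scores))))
  fractions <- sweep(unclass(tab), 1, rowSums(tab), "/")
  list(states = stats::setNames(lab, rownames(scores)),
       fractions = fractions, scores = scores)
}

#' Wilcoxon differential expression between two cell populations
#'
#' Per gene expressed in at least one of the two populations: natural-log
#' fold change of the de-logged means,
#' `ln((mean(expm1 x_A) + 1) / (mean(expm1 x_B) + 1))`, and a two-sided
#' Wilcoxon rank-sum p-value (exact for small tie-free samples, normal
#' approximation with tie correction otherwise), Bonferroni-adjusted over
#' the tested genes. Significance requires `|lfc| > lfcThreshold`
#' (strict) and `p_adj < alpha`.
#'
#' @param ce a [CellExperiment-class] with `"logcounts"`.
#' @param cellsA,cellsB column ids of the two populations (>= 3 each).
#' @param lfcThreshold natural-log fold-change threshold (default 0.2).
#' @param alpha adjusted-significance level (default 0.05).
#' @return DataFrame with `gene`, `lfc`, `p`, `p_adj`, `significant`;
#'   untestable genes (expressed in neither group) are reported in
#'   `attr(, "skipped")`.
#' @export
stateDE <- function(ce, cellsA, cellsB, lfcThreshold = 0.2, alpha = 0.05) {
  x <- assay(ce, "logcounts")
  xa <- as.matrix(x[, cellsA, drop = FALSE])
  xb <- as.matrix(x[, cellsB, drop = FALSE])
  if (ncol(xa) < 3 || ncol(xb) < 3) stop("need >= 3 cells per side")
  expressed <- rowSums(xa) > 0 | rowSums(xb) > 0
  skipped <- rownames(x)[!expressed]
  xa <- xa[expressed, , drop = FALSE]
  xb <- xb[expressed, , drop = FALSE]
  lfc <- as.numeric(log((rowMeans(expm1(xa)) + 1) /
                      (rowMeans(expm1(xb)) + 1)))
  p <- vapply(seq_len(nrow(xa)), function(i)
    suppressWarnings(stats::wilcox.test(xa[i, ], xb[i, ])$p.value),
    numeric(1))
  padj <- stats::p.adjust(p, method = "bonferroni")
  res <- DataFrame(gene = rownames(xa), lfc = lfc, p = p, p_adj = padj,
                   significant = abs(lfc) > lfcThreshold & padj < alpha)
  attr(res, "skipped") <- skipped
  res
}

#' Concordance of two state DE results
#'
#' Spearman correlation of the log fold changes over genes significant in
#' either result (and present in both) - the cross-strain comparison of
#' the activated-versus-homeostatic signature.
#'
#' @param resA,resB DataFrames from [stateDE()].
#' @return list with `rho`, `p`, `n`.
#' @export
stateDeConcordance <- function(resA, resB) {
  shared <- intersect(resA$gene, resB$gene)
  a <- resA[match(shared, resA$gene), ]
  b <- resB[match(shared, resB$gene), ]
  sel <- a$significant | b$significant
  if (sum(sel) < 3) stop("fewer than 3 shared significant genes")
  ct <- suppressWarnings(stats::cor.test(a$lfc[sel], b$lfc[sel],
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(sel))
}
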