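#' @include AllClasses.R bulkDE.R
NULL

#' Per-group state mean expression of genes in single-cell data
#'
#' For each gene and experimental group, the mean normalized expression
#' over all microglial cells (`mu_all`), over homeostatic cells (`mu_HM`)
#' and over all non-homeostatic cells (`mu_ARMplus`). Compartments with no
#' cell in a group are returned as `NA` (missing-flagged).
#'
#' @param ce a [CellExperiment-class] with `"logcounts"`.
#' @param states per-cell state labels (e.g. from [assignStates()]).
#' @param genes gene ids to summarize (must exist in the matrix).
#' @param homeostaticStates state labels counted as homeostatic
#'   (default `"HM"`; pass several to pool sub-clusters).
#' @return list of three gene-by-group matrices: `muAll`, `muHM`,
#'   `muARMplus`.
#' @export
stateMeanExpression <- function(ce, states, genes,
                                homeostaticStates = "HM") {
  x <- assay(ce, "logcounts")
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("gene(s) absent from the single-cell matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  grp <- colData(ce)$group
  groups <- unique(grp)
  isHM <- states %in% homeostaticStates
  mk <- function(sel) {
    m <- vapply(groups, function(g) {
      cols <- which(grp == g & sel)
      if (!length(cols)) return(rep(NA_real_, length(genes)))
      Matrix::rowMeans(x[genes, cols, drop = FALSE])
    }, numeric(length(genes)))
    matrix(m, nrow = length(genes))
  }
  out <- list(muAll = mk(rep(TRUE, ncol(x))), muHM = mk(isHM),
              muARMplus = mk(!isHM))
  out <- lapply(out, function(m) {
    dimnames(m) <- list(genes, groups); m
  })
  out
}

#' Microgliosis index from bulk marker-gene z-scores
#'
#' The mean baseline-anchored z-score of the microglia marker genes per
#' experimental group, shifted so the lowest group sits at 1:
#' `M_g = raw_g - min(raw) + 1`. The additive convention is the default
#' because mean z-scores can be negative, making a ratio ill-defined; a
#' divisive alternative (`raw / min(raw)`, requiring all-positive raws) is
#' available.
#'
#' @param z z-matrix from [znormToBaseline()].
#' @param microgliaSet character marker set.
#' @param groups named list: group label -> column ids.
#' @param normalize `"additive"` (default) or `"divisive"`.
#' @return list with `raw` and `M` (named per group; `min(M) == 1`).
#' @export
microgliosisIndex <- function(z, microgliaSet, groups,
                              normalize = c("additive", "divisive")) {
  normalize <- match.arg(normalize)
  if (length(groups) < 2) stop("need at least 2 groups")
  gs <- intersect(microgliaSet, rownames(z))
  if (!length(gs)) stop("microglia set has no member in the z-matrix")
  raw <- vapply(groups, function(idx)
    mean(z[gs, idx, drop = FALSE]), numeric(1))
  M <- if (normalize == "additive") raw - min(raw) + 1 else {
    if (min(raw) <= 0)
      stop("divisive normalization requires all-positive group means")
    raw / min(raw)
  }
  list(raw = raw, M = M)
}

#' Predicted bulk expression from microgliosis and state composition
#'
#' `P_g = M_g * (f_HM(g) mu_HM(g) + f_ARM+(g) mu_ARM+(g))`: the microglial
#' contribution to bulk expression of a gene, combining overall microglial
#' abundance with the homeostatic/activated split. Missing compartment
#' means contribute 0 with a warning.
#'
#' @param M named microgliosis index per group.
#' @param fractions group-by-state matrix with columns `HM` and `ARM`
#'   (rows over the groups of `M`, summing to 1).
#' @param muHM,muARM gene-by-group state mean matrices.
#' @return gene-by-group matrix of predicted expression.
#' @export
predictedBulk <- function(M, fractions, muHM, muARM) {
  groups <- names(M)
  stopifnot(!is.null(groups), all(groups %in% rownames(fractions)),
            all(groups %in% colnames(muHM)),
            all(groups %in% colnames(muARM)))
  f <- fractions[groups, , drop = FALSE]
  if (any(f < 0) || any(M < 0)) stop("negative fractions or index")
  if (any(abs(rowSums(f[, c("HM", "ARM"), drop = FALSE]) - 1) > 1e-9))
    stop("fractions must sum to 1 per group")
  mh <- muHM[, groups, drop = FALSE]
  ma <- muARM[, groups, drop = FALSE]
  if (anyNA(mh) || anyNA(ma)) {
    warning("missing compartment means contribute 0 to the prediction")
    mh[is.na(mh)] <- 0
    ma[is.na(ma)] <- 0
  }
  if (any(mh < 0, na.rm = TRUE) || any(ma < 0, na.rm = TRUE))
    stop("negative state means")
  bracket <- t(f[, "HM"] * t(mh) + f[, "ARM"] * t(ma))
  t(M * t(bracket))
}

#' Regress observed bulk expression on the microglial prediction
#'
#' Per gene, ordinary least squares of the observed per-group bulk means on
#' the predicted expression (with intercept, since bulk contains
#' non-microglial background signal); reports the coefficient of
#' determination r2, the two-sided slope p-value, BY adjustment across the
#' gene panel, and the explained flag `r2 >= r2Threshold & p_adj < alpha`
#' (the "explained by microglia" rule, default threshold 0.67). When `M`
#' and the composition term are supplied, a first-order variance
#' decomposition attributes the predicted variation to microgliosis versus
#' state-fraction change by holding the other factor at its group mean.
#'
#' @param predicted gene-by-group matrix from [predictedBulk()].
#' @param observed gene-by-group matrix of observed bulk means (same
#'   dimnames).
#' @param r2Threshold explained-variance threshold (default 0.67).
#' @param alpha significance level on the BY-adjusted p (default 0.05).
#' @param M optional named microgliosis index (enables the driver
#'   decomposition).
#' @param stateTerm optional gene-by-group matrix of the composition term
#'   `f_HM mu_HM + f_ARM+ mu_ARM+`.
#' @return DataFrame with `gene`, `r2`, `p`, `p_adj`, `explained`,
#'   `reason`, and - when decomposable - `driver_share_microgliosis`.
#' @export
fitContribution <- function(predicted, observed, r2Threshold = 0.67,
                            alpha = 0.05, M = NULL, stateTerm = NULL) {
  stopifnot(identical(dim(predicted), dim(observed)))
  if (ncol(predicted) < 4) stop("need >= 4 groups for the regression")
  genes <- rownames(predicted)
  n <- ncol(predicted)
  fitOne <- function(pg, og) {
    if (stats::var(pg) == 0)
      return(c(r2 = NA_real_, p = NA_real_))
    f <- stats::lm(og ~ pg)
    sm <- summary(f)
    c(r2 = sm$r.squared, p = sm$coefficients["pg", "Pr(>|t|)"])
  }
  st <- t(vapply(seq_along(genes), function(i)
    fitOne(predicted[i, ], observed[i, ]), numeric(2)))
  ok <- !is.na(st[, "p"])
  padj <- rep(NA_real_, length(genes))
  padj[ok] <- adjustBY(st[ok, "p"])
  explained <- !is.na(st[, "r2"]) & st[, "r2"] >= r2Threshold &
    !is.na(padj) & padj < alpha
  reason <- rep(NA_character_, length(genes))
  reason[!ok] <- "zero_prediction_variance"
  res <- DataFrame(gene = genes, r2 = st[, "r2"], p = st[, "p"],
                   p_adj = padj, explained = explained, reason = reason)
  if (!is.null(M) && !is.null(stateTerm)) {
    groups <- colnames(predicted)
    Mv <- M[groups]
    res$driver_share_microgliosis <- vapply(genes, function(g) {
      b <- stateTerm[g, groups]
      vM <- stats::var(Mv * mean(b))       # microgliosis varying, term fixed
      vB <- stats::var(mean(Mv) * b)       # term varying, microgliosis fixed
      if (vM + vB == 0) return(NA_real_)
      vM / (vM + vB)
    }, numeric(1))
  }
  res
}

#' End-to-end microglial-contribution analysis for a gene panel
#'
#' Convenience wrapper chaining [stateMeanExpression()],
#' [microgliosisIndex()], [predictedBulk()] and [fitContribution()] for a
#' panel of candidate genes: single-cell state means are de-logged
#' (`expm1`) to linear scale before mixing, and observed bulk means are the
#' per-group means of linear-scale CPM from the normalized bulk assay.
#'
#' @param ce a [CellExperiment-class] with `"logcounts"` and state labels.
#' @param states per-cell state labels.
#' @param be a [BulkExperiment-class] with `"logcpm"`.
#' @param z baseline-anchored z-matrix of the bulk data.
#' @param microgliaSet marker gene set for the microgliosis index.
#' @param fractions group-by-state fractions from [assignStates()].
#' @param genes candidate gene panel (must be present in both datasets).
#' @param groups named list: group label -> bulk column ids.
#' @param ... passed to [fitContribution()].
#' @return the [fitContribution()] DataFrame.
#' @export
deconvolveGenes <- function(ce, states, be, z, microgliaSet, fractions,
                            genes, groups, ...) {
  sm <- stateMeanExpression(ce, states, genes)
  mi <- microgliosisIndex(z, microgliaSet, groups)
  shared <- intersect(names(mi$M), colnames(sm$muHM))
  if (length(shared) < 4) stop("fewer than 4 shared groups")
  M <- mi$M[shared]
  muHM <- expm1(sm$muHM[, shared, drop = FALSE])
  muARM <- expm1(sm$muARMplus[, shared, drop = FALSE])
  pred <- predictedBulk(M, fractions, muHM, muARM)
  lc <- assay(be, "logcpm")
  obs <- vapply(shared, function(g)
    rowMeans(2^lc[genes, groups[[g]], drop = FALSE]),
    numeric(length(genes)))
  f <- fractions[shared, , drop = FALSE]
  mh <- muHM; ma <- muARM
  mh[is.na(mh)] <- 0; ma[is.na(ma)] <- 0
  stateTerm <- t(f[, "HM"] * t(mh) + f[, "ARM"] * t(ma))
  fitContribution(pred, obs, M = M, stateTerm = stateTerm, ...)
}
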