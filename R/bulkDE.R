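#' @include AllClasses.R
#' @importFrom limma removeBatchEffect
NULL

#' Filter genes by minimum mean raw count support
#'
#' Retains genes whose average raw read count exceeds `minMean` in at least
#' `minSamples` samples, the low-expression rule used before differential
#' expression (the canonical setting discards mRNAs with average raw counts
#' <= 5 in 10 out of 96 samples). Gene order is preserved.
#'
#' @param be a [BulkExperiment-class].
#' @param minMean count threshold; a gene must exceed it (`> minMean`).
#' @param minSamples number of samples in which the threshold must be
#'   exceeded.
#' @return the filtered [BulkExperiment-class]; warns (not errors) when no
#'   gene survives.
#' @export
filterLowCounts <- function(be, minMean = 5, minSamples = 10) {
  stopifnot(minMean >= 0, minSamples >= 0)
  cts <- assay(be, "counts")
  keep <- rowSums(cts > minMean) >= minSamples
  if (!any(keep)) warning("no genes pass the low-count filter")
  be[keep, ]
}

#' Log2 counts-per-million normalization
#'
#' `value = log2(1e6 * count / librarySize + pseudocount)`. The library
#' size is the sample's total raw count. Stored as assay `"logcpm"`; the
#' library sizes are kept in `metadata(x)$librarySizes`.
#'
#' @param be a [BulkExperiment-class].
#' @param pseudocount positive stabilizer added on the CPM scale
#'   (default 0.5, the conventional voom-style offset).
#' @return `be` with an added `"logcpm"` assay.
#' @export
normalizeLogCpm <- function(be, pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  cts <- assay(be, "counts")
  lib <- colSums(cts)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(cts)[lib == 0], collapse = ", "))
  assay(be, "logcpm") <- log2(t(t(cts) / lib) * 1e6 + pseudocount)
  metadata(be)$librarySizes <- lib
  metadata(be)$pseudocount <- pseudocount
  be
}

.designMatrix <- function(df, vars) {
  if (!length(vars)) return(NULL)
  f <- stats::as.formula(paste("~", paste(vars, collapse = " + ")))
  stats::model.matrix(f, data = as.data.frame(df))
}

#' Remove technical covariates from the normalized matrix
#'
#' Per gene, subtracts the fitted nuisance component (library-prep batch and
#' similar factors, plus scalar covariates such as RNA concentration) from a
#' joint least-squares fit that protects the biological design, so that
#' protected effects are unchanged. This is the classical
#' `limma::removeBatchEffect` operation; rank deficiency between nuisance
#' and protected columns is detected first and reported with the aliased
#' columns.
#'
#' @param be a [BulkExperiment-class] with a `"logcpm"` assay.
#' @param nuisance character; `colData` columns to remove (factors or
#'   numeric).
#' @param protect character; `colData` columns spanning the biological
#'   design to preserve (default `age`, `genotype` and their interaction via
#'   the `group` column when present).
#' @return `be` with the `"logcpm"` assay residualized.
#' @export
residualizeCovariates <- function(be, nuisance = c("batch", "concentration"),
                                  protect = c("age", "genotype")) {
  stopifnot("logcpm" %in% assayNames(be))
  cd <- as.data.frame(colData(be))
  stopifnot(all(nuisance %in% colnames(cd)), all(protect %in% colnames(cd)))
  isFac <- vapply(cd[nuisance], function(x)
    is.character(x) || is.factor(x), logical(1))
  facVars <- nuisance[isFac]
  numVars <- nuisance[!isFac]

  protMat <- .designMatrix(cd, protect)
  nuiMat <- .designMatrix(cd, nuisance)
  full <- cbind(protMat, nuiMat[, -1, drop = FALSE])
  qrF <- qr(full)
  if (qrF$rank < ncol(full)) {
    aliased <- colnames(full)[qrF$pivot[(qrF$rank + 1):ncol(full)]]
    stop("nuisance design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  x <- assay(be, "logcpm")
  batchArgs <- list(x = x, design = protMat)
  if (length(facVars) >= 1) batchArgs$batch <- cd[[facVars[1]]]
  if (length(facVars) >= 2) batchArgs$batch2 <- cd[[facVars[2]]]
  if (length(facVars) > 2)
    stop("at most two categorical nuisance factors are supported")
  if (length(numVars))
    batchArgs$covariates <- as.matrix(cd[numVars])
  assay(be, "logcpm") <- do.call(limma::removeBatchEffect, batchArgs)
  be
}

.contrastWeights <- function(style) {
  # group order: WT4, WT10, TG4, TG10
  list(
    age = c(-0.5, 0.5, -0.5, 0.5),
    genotype = c(-0.5, -0.5, 0.5, 0.5),
    age_x_genotype = if (style == "fig1c")
      c(-1 / 3, -1 / 3, -1 / 3, 1) else c(1, -1, -1, 1))
}

#' Fit the 2x2 age-by-genotype model per gene for one strain
#'
#' Ordinary least squares on the four group means with two-sided t-tests on
#' three contrasts: `age` (10M - 4M), `genotype` (TG - WT), and the
#' interaction. Under `contrastStyle = "fig1c"` the interaction contrast is
#' TG-10M versus the mean of the other three groups (which transcripts are
#' differentially expressed in aged transgenics compared to all other
#' groups); `"classical"` is the textbook difference-in-differences
#' `(TG10 - TG4) - (WT10 - WT4)`. P-values are BY-adjusted within each
#' contrast and the signed `-log10 p` ranking metric is attached.
#'
#' @param be a [BulkExperiment-class] with a `"logcpm"` assay, restricted to
#'   a single strain (subset first when the object holds both).
#' @param contrastStyle `"fig1c"` (default) or `"classical"`.
#' @return DataFrame with columns `gene`, `contrast`, `lfc`, `p`, `p_adj`,
#'   `metric`.
#' @export
fitTwoByTwo <- function(be, contrastStyle = c("fig1c", "classical")) {
  contrastStyle <- match.arg(contrastStyle)
  stopifnot("logcpm" %in% assayNames(be))
  cd <- colData(be)
  if (length(unique(cd$strain)) != 1)
    stop("fit one strain at a time; subset the experiment first")
  grp <- factor(paste(cd$genotype, cd$age, sep = "."),
                levels = c("WT.4M", "WT.10M", "TG.4M", "TG.10M"))
  if (any(table(grp) == 0))
    stop("empty design cell(s): ",
         paste(levels(grp)[table(grp) == 0], collapse = ", "))
  x <- assay(be, "logcpm")
  n <- ncol(x)
  ng <- table(grp)

  ind <- stats::model.matrix(~ 0 + grp)
  means <- x %*% ind %*% diag(1 / as.numeric(ng))  # gene x 4 group means
  fitted <- means %*% t(ind)
  rss <- rowSums((x - fitted)^2)
  df <- n - 4L
  s2 <- rss / df

  w <- .contrastWeights(contrastStyle)
  out <- lapply(names(w), function(cn) {
    cw <- w[[cn]]
    est <- as.numeric(means %*% cw)
    se <- sqrt(s2 * sum(cw^2 / as.numeric(ng)))
    tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
    p <- 2 * stats::pt(-abs(tstat), df)
    DataFrame(gene = rownames(x), contrast = cn, lfc = est, p = p)
  })
  res <- do.call(rbind, out)
  res$p_adj <- NA_real_
  for (cn in names(w)) {
    i <- res$contrast == cn
    res$p_adj[i] <- adjustBY(res$p[i])
  }
  res$metric <- .signedLog10(res$p, res$lfc)
  res
}

.signedLog10 <- function(p, lfc) {
  if (any(p <= 0)) {
    warning("p-values of 0 floored at 1e-300 before log10")
    p <- pmax(p, 1e-300)
  }
  ifelse(lfc > 0, 1, ifelse(lfc < 0, -1, 0)) * (-log10(p))
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up Benjamini-Hochberg multiplied by the harmonic constant
#' `c(m) = sum(1/i, i = 1..m)`, clipped at 1 - the FDR control valid under
#' arbitrary dependence. Delegates to `stats::p.adjust(method = "BY")`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return BY-adjusted p-values, monotone non-decreasing in rank order.
#' @examples
#' adjustBY(c(0.01, 0.02, 0.03))  # all 0.03 * 11/6 = 0.055
#' @export
adjustBY <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Signed -log10(p) ranking of a DE result
#'
#' The ranking metric is `sign(lfc) * -log10(p)` on the unadjusted p-value;
#' p-values of exactly 0 are floored at 1e-300 with a warning. The returned
#' table is sorted most-upregulated to most-downregulated.
#'
#' @param de DataFrame from [fitTwoByTwo()].
#' @param contrast which contrast to rank (default the interaction).
#' @return DataFrame with `gene` and `metric`, sorted decreasing.
#' @export
signedRanking <- function(de, contrast = "age_x_genotype") {
  d <- de[de$contrast == contrast, ]
  if (!nrow(d)) stop("no rows for contrast ", contrast)
  metric <- .signedLog10(d$p, d$lfc)
  o <- order(metric, decreasing = TRUE)
  DataFrame(gene = d$gene[o], metric = metric[o])
}

#' Spearman correlation between two strains' DE rankings
#'
#' Restricts to the union of genes significant (`p_adj < alpha`) in either
#' result for the chosen contrast, then computes the two-sided Spearman
#' correlation of the signed -log10(p) metrics with a Fisher-z 95%
#' confidence interval. Ties get average ranks; the p-value uses the t
#' approximation.
#'
#' @param resA,resB DataFrames from [fitTwoByTwo()] for the two strains.
#' @param contrast contrast to compare.
#' @param alpha significance level for the subset rule.
#' @return list with `rho`, `p`, `ci` (length-2), `n`.
#' @export
rankCorrelation <- function(resA, resB, contrast = "age_x_genotype",
                            alpha = 0.05) {
  a <- resA[resA$contrast == contrast, ]
  b <- resB[resB$contrast == contrast, ]
  shared <- intersect(a$gene, b$gene)
  a <- a[match(shared, a$gene), ]
  b <- b[match(shared, b$gene), ]
  sel <- a$p_adj < alpha | b$p_adj < alpha
  if (sum(sel) < 3) stop("fewer than 3 genes significant in either result")
  ct <- suppressWarnings(
    stats::cor.test(a$metric[sel], b$metric[sel], method = "spearman",
                    exact = FALSE))
  rho <- unname(ct$estimate)
  n <- sum(sel)
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  hw <- stats::qnorm(0.975) / sqrt(n - 3)
  list(rho = rho, p = ct$p.value, ci = tanh(c(z - hw, z + hw)), n = n)
}
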