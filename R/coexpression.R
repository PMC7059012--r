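#' @include AllClasses.R
NULL

.dropConstantGenes <- function(x) {
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) excluded from the network")
    x <- x[sds > 0, , drop = FALSE]
  }
  x
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power beta, forms the unsigned adjacency
#' `|cor|^beta`, computes connectivities `k_i`, bins them into 10
#' equal-count bins, and fits `log10 p(k) ~ log10 mean(k)`; the signed fit
#' index is `R^2 * -sign(slope)`. Returns the smallest power whose signed
#' R^2 reaches `r2Target` (classically 0.9), or the power with maximal
#' signed R^2 with a warning when none does.
#'
#' @param x gene-by-sample normalized expression matrix (>= 8 samples).
#' @param powers ascending candidate powers.
#' @param r2Target scale-free fit threshold in `(0, 1]`.
#' @param nBins number of equal-count connectivity bins.
#' @return list with `beta` and `fitTable` (data.frame: `power`,
#'   `signedR2`, `meanK`).
#' @export
pickSoftPower <- function(x, powers = 1:10, r2Target = 0.9, nBins = 10) {
  stopifnot(ncol(x) >= 8, !is.unsorted(powers), r2Target > 0, r2Target <= 1)
  x <- .dropConstantGenes(x)
  ac <- abs(stats::cor(t(x)))
  diag(ac) <- 0
  fit <- lapply(powers, function(beta) {
    k <- rowSums(ac^beta)
    data.frame(power = beta, signedR2 = .scaleFreeR2(k, nBins),
               meanK = mean(k))
  })
  fitTable <- do.call(rbind, fit)
  ok <- fitTable$signedR2 >= r2Target
  if (any(ok)) beta <- fitTable$power[which(ok)[1]]
  else {
    beta <- fitTable$power[which.max(fitTable$signedR2)]
    warning("no candidate power reaches the scale-free fit target ",
            r2Target, "; returning the best (beta = ", beta, ")")
  }
  list(beta = beta, fitTable = fitTable)
}

.scaleFreeR2 <- function(k, nBins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = nBins + 1)))
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  # equal-count bins: the degree density is count / (n * bin width)
  width <- diff(br)
  pk <- as.numeric(table(bin)) / (length(k) * width)
  keep <- !is.na(dk) & pk > 0 & width > 0
  if (sum(keep) < 3) return(NA_real_)
  f <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(f)$r.squared
  unname(r2 * -sign(stats::coef(f)[2]))
}

#' Unsigned adjacency and topological overlap matrix
#'
#' Adjacency `a_ij = |cor(i, j)|^beta` (diagonal zeroed for connectivity),
#' topological overlap
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj`, and `TOM_ii = 1`. The clustering dissimilarity
#' is `1 - TOM`.
#'
#' @param x gene-by-sample normalized expression matrix with no constant
#'   genes.
#' @param beta soft-threshold power.
#' @return symmetric TOM matrix in `[0, 1]` with unit diagonal; the
#'   adjacency is attached as `attr(, "adjacency")`.
#' @export
adjacencyTom <- function(x, beta) {
  stopifnot(beta >= 1)
  cc <- stats::cor(t(x))
  if (any(abs(cc) > 1 + 1e-12) || any(is.na(cc)))
    stop("correlations outside [-1, 1] (constant gene?)")
  a <- abs(pmin(pmax(cc, -1), 1))^beta
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom <- pmin(pmax((tom + t(tom)) / 2, 0), 1)
  dimnames(tom) <- dimnames(a)
  attr(tom, "adjacency") <- a
  tom
}

#' Module eigengene: first principal component across samples
#'
#' The eigengene of a module is the first principal component of the
#' gene-standardized submatrix, one score per sample, oriented so that its
#' correlation with the module's mean standardized expression profile is
#' positive. When that mean profile is degenerate (near zero, e.g. two
#' genes that are exact negations), the sign is fixed so the loading of the
#' lexicographically first module gene is positive.
#'
#' @param x gene-by-sample normalized expression matrix.
#' @param genes module member gene ids (>= 2).
#' @return numeric vector of per-sample eigengene scores (unit norm);
#'   `attr(, "varExplained")` carries the PC1 variance fraction.
#' @export
moduleEigengene <- function(x, genes) {
  stopifnot(length(genes) >= 2, ncol(x) >= 2)
  sub <- x[intersect(genes, rownames(x)), , drop = FALSE]
  if (nrow(sub) < 2) stop("fewer than 2 module genes found in the matrix")
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning("constant module gene(s) dropped from eigengene computation")
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) < 2) stop("fewer than 2 non-constant module genes")
  }
  z <- t(scale(t(sub)))
  sv <- svd(z)
  me <- sv$v[, 1]
  meanProfile <- colMeans(z)
  or <- if (stats::sd(meanProfile) > 1e-10)
    sum(me * (meanProfile - mean(meanProfile))) else 0
  if (abs(or) > 1e-10) {
    if (or < 0) me <- -me
  } else {
    first <- order(rownames(z))[1]
    if (sv$u[first, 1] < 0) me <- -me
  }
  names(me) <- colnames(x)
  attr(me, "varExplained") <- sv$d[1]^2 / sum(sv$d^2)
  me
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut statically at
#' a configurable dissimilarity height; clusters smaller than
#' `minModuleSize` become `"unassigned"`; modules whose eigengenes
#' correlate above `mergeCorr` are merged iteratively; membership is then
#' refined by eigengene correlation (kME). Labels are `"M1"`, `"M2"`, ...
#' ordered by decreasing size - deterministic given the inputs.
#'
#' @param tom topological overlap matrix from [adjacencyTom()].
#' @param x gene-by-sample expression matrix (for eigengene-based merging
#'   and the returned eigengene profiles).
#' @param minModuleSize smallest module kept (default 30).
#' @param cutHeight static cut height on the 1 - TOM dissimilarity scale
#'   (default 0.95): subtrees completing below it become candidate
#'   modules, while the near-1 background plateau stays uncut.
#' @param mergeCorr eigengene correlation above which modules merge
#'   (default 0.75).
#' @param kmeThreshold minimum signed gene-eigengene correlation (module
#'   membership, kME, relative to the positively oriented eigengene) for
#'   final module assignment (default 0.5): after merging, genes are
#'   reassigned to the module whose eigengene they correlate with best,
#'   pruning noise the static cut accreted (including compositionally
#'   anti-correlated background) and adopting genuine members it stranded.
#'   Set above 1 to disable.
#' @return a [ModulePartition-class]; warns and returns an all-unassigned
#'   partition when nothing survives the size filter.
#' @export
detectModules <- function(tom, x, minModuleSize = 30, cutHeight = 0.95,
                          mergeCorr = 0.75, kmeThreshold = 0.5) {
  genes <- rownames(tom)
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(h, h = cutHeight)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= minModuleSize]
  labels <- ifelse(cl %in% as.integer(keep), paste0("c", cl), "unassigned")
  names(labels) <- genes
  if (!length(keep)) {
    warning("all genes unassigned (no cluster reaches minModuleSize)")
    return(new("ModulePartition",
               labels = stats::setNames(rep("unassigned", length(genes)),
                                        genes),
               eigengenes = matrix(numeric(), 0, ncol(x),
                                   dimnames = list(NULL, colnames(x))),
               tom = tom, fitTable = data.frame()))
  }

  # unsigned topology can fuse anti-correlated gene groups into one
  # cluster; split such clusters by the sign of the gene-eigengene
  # correlation so each candidate module is coherent
  for (m in setdiff(unique(labels), "unassigned")) {
    g <- names(labels)[labels == m]
    if (length(g) < 2 * minModuleSize) next
    me <- moduleEigengene(x, g)
    sgn <- as.numeric(stats::cor(t(x[g, , drop = FALSE]), me))
    neg <- g[sgn < 0]
    if (length(neg) >= minModuleSize &&
        length(g) - length(neg) >= minModuleSize)
      labels[neg] <- paste0(m, "neg")
  }

  repeat {
    mods <- setdiff(unique(labels), "unassigned")
    if (length(mods) < 2) break
    mes <- vapply(mods, function(m)
      moduleEigengene(x, names(labels)[labels == m]), numeric(ncol(x)))
    cm <- stats::cor(mes)
    diag(cm) <- -Inf
    if (max(cm) <= mergeCorr) break
    top <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    from <- mods[top[2]]; to <- mods[top[1]]
    labels[labels == from] <- to
  }

  # kME refinement: membership is the signed correlation with the oriented
  # module eigengene; genes below the threshold are pruned (tree-cut
  # accretion, including compositionally anti-correlated background),
  # unassigned genes above it are adopted (tree-cut stragglers)
  mods <- setdiff(unique(labels), "unassigned")
  if (length(mods)) {
    mes <- vapply(mods, function(m)
      moduleEigengene(x, names(labels)[labels == m]), numeric(ncol(x)))
    kme <- stats::cor(t(x), mes)
    best <- max.col(kme, ties.method = "first")
    bestVal <- kme[cbind(seq_len(nrow(kme)), best)]
    labels <- ifelse(bestVal >= kmeThreshold, mods[best], "unassigned")
    names(labels) <- genes
    sizes <- table(labels[labels != "unassigned"])
    small <- names(sizes)[sizes < minModuleSize]
    labels[labels %in% small] <- "unassigned"
  }

  mods <- setdiff(unique(labels), "unassigned")
  ord <- mods[order(-vapply(mods, function(m) sum(labels == m), numeric(1)),
                    mods)]
  newNames <- stats::setNames(paste0("M", seq_along(ord)), ord)
  labels[labels != "unassigned"] <- newNames[labels[labels != "unassigned"]]
  mes <- t(vapply(paste0("M", seq_along(ord)), function(m)
    moduleEigengene(x, names(labels)[labels == m]), numeric(ncol(x))))
  colnames(mes) <- colnames(x)
  new("ModulePartition", labels = labels, eigengenes = mes, tom = tom,
      fitTable = data.frame())
}
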