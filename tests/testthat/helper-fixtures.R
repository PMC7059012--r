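# Shared fixture builders; everything is generated in code at test time.

# BulkExperiment for one strain with exact per-group logcpm means.
# groupMeans: named c(WT4=, WT10=, TG4=, TG10=) per gene (list of vectors or
# a gene x 4 matrix); noise: function(n) residuals added per sample.
toyBulk <- function(groupMeans, nPerGroup = 3, noise = function(n) rep(0, n),
                    strain = "APP") {
  gm <- if (is.matrix(groupMeans)) groupMeans else
    matrix(groupMeans, nrow = 1,
           dimnames = list("g1", names(groupMeans)))
  stopifnot(identical(colnames(gm), c("WT4", "WT10", "TG4", "TG10")))
  design <- data.frame(
    strain = strain,
    genotype = rep(c("WT", "WT", "TG", "TG"), each = nPerGroup),
    age = rep(c("4M", "10M", "4M", "10M"), each = nPerGroup))
  design$group <- paste0(strain, tolower(design$genotype), "_", design$age)
  n <- nrow(design)
  x <- t(apply(gm, 1, function(mu)
    rep(mu, each = nPerGroup) + noise(n)))
  if (nrow(gm) == 1) x <- matrix(x, nrow = 1)
  colnames(x) <- sprintf("s%02d", seq_len(n))
  rownames(x) <- rownames(gm)
  rownames(design) <- colnames(x)
  counts <- matrix(1L, nrow(x), ncol(x), dimnames = dimnames(x))
  be <- BulkExperiment(counts, design)
  SummarizedExperiment::assay(be, "logcpm") <- x
  be
}

# Balanced +/- residuals so group means stay exact but residual variance > 0
symNoise <- function(n) rep(c(1, -1), length.out = n)

# Naive triple-loop TOM oracle from an adjacency matrix (diag 0)
tomOracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# Brute-force O(N * |S|) running-sum enrichment oracle
esOracle <- function(metric, hit, p = 1) {
  n <- length(metric)
  nh <- sum(hit)
  w <- abs(metric)^p
  denomHit <- sum(w[hit])
  rs <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) w[i] / denomHit else -1 / (n - nh)
    rs[i] <- cur
  }
  rs[which.max(abs(rs))]
}

# Expression matrix with planted correlated blocks: each block follows one
# latent factor with residual sd chosen to hit the target correlation.
blockExpr <- function(blockSizes, nSamples = 40, rho = 0.9, nNoise = 0,
                      seed = 1) {
  withr::with_seed(seed, {
    nGenes <- sum(blockSizes) + nNoise
    x <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples)
    resSd <- sqrt(1 / rho - 1)
    at <- 0
    for (b in seq_along(blockSizes)) {
      z <- rnorm(nSamples)
      idx <- at + seq_len(blockSizes[b])
      x[idx, ] <- matrix(rep(z, each = blockSizes[b]),
                         blockSizes[b]) + resSd * x[idx, ]
      at <- at + blockSizes[b]
    }
    dimnames(x) <- list(sprintf("g%04d", seq_len(nGenes)),
                        sprintf("s%02d", seq_len(nSamples)))
    x
  })
}

# Adjusted Rand index between two labelings
randIndex <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  (sumij - expected) / ((sumi + sumj) / 2 - expected)
}

# Tiny CellExperiment with fully controlled totals and mito fractions
toyCells <- function(totals, mitoFracs, nGenes = 10, groups = NULL) {
  stopifnot(length(totals) == length(mitoFracs))
  nc <- length(totals)
  genes <- c(sprintf("g%02d", seq_len(nGenes - 1)), "mt-1")
  m <- matrix(0, nGenes, nc, dimnames = list(genes,
                                             sprintf("c%02d", seq_len(nc))))
  for (i in seq_len(nc)) {
    mito <- round(totals[i] * mitoFracs[i])
    rest <- totals[i] - mito
    m["mt-1", i] <- mito
    m[seq_len(nGenes - 1), i] <- c(rest, rep(0, nGenes - 2))
  }
  if (is.null(groups)) groups <- rep("G1", nc)
  CellExperiment(m, groups = groups, mitoGenes = "mt-1")
}

# Exhaustive enumeration oracle: iterate over all placements of each set
# (as combinations of the background) and tabulate intersection sizes.
enumOracle <- function(N, sizes) {
  sets <- lapply(sizes, function(n) utils::combn(N, n, simplify = FALSE))
  counts <- numeric(min(sizes) + 1)
  grid <- expand.grid(lapply(sets, seq_along))
  for (r in seq_len(nrow(grid))) {
    pick <- lapply(seq_along(sizes), function(j) sets[[j]][[grid[r, j]]])
    x <- length(Reduce(intersect, pick))
    counts[x + 1] <- counts[x + 1] + 1
  }
  counts / sum(counts)
}

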