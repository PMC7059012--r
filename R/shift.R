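#' @include AllClasses.R utils.R
NULL

#' Baseline-anchored z-normalization of bulk expression
#'
#' Centers each gene on its mean over the baseline samples (classically the
#' wild-type 4-month group of the same strain) and scales by the gene's
#' standard deviation over all samples:
#' `Z_is = (E_is - mean_baseline(E_i)) / sd_all(E_i)`. Genes with zero
#' overall sd are excluded with a warning.
#'
#' @param x gene-by-sample normalized expression matrix.
#' @param baselineSamples column ids (or logical/integer index) of the
#'   baseline group; at least 2.
#' @return gene-by-sample z-matrix; excluded genes recorded in
#'   `attr(, "excluded")`.
#' @export
znormToBaseline <- function(x, baselineSamples) {
  if (is.character(baselineSamples))
    baselineSamples <- match(baselineSamples, colnames(x))
  if (anyNA(baselineSamples)) stop("unknown baseline sample(s)")
  b <- x[, baselineSamples, drop = FALSE]
  if (ncol(b) < 2) stop("baseline needs >= 2 samples")
  sdAll <- apply(x, 1, stats::sd)
  excluded <- rownames(x)[sdAll == 0]
  if (length(excluded))
    warning(length(excluded), " zero-sd gene(s) excluded from z-scoring")
  keep <- sdAll > 0
  z <- (x[keep, , drop = FALSE] - rowMeans(b[keep, , drop = FALSE])) /
    sdAll[keep]
  attr(z, "excluded") <- excluded
  z
}

#' Mean z-score of a gene set in an experimental group
#'
#' The composition-shift statistic `Z_tg`: the arithmetic mean of the
#' per-gene z-scores over all genes of a cell-type set and all samples of
#' an experimental group.
#'
#' @param z z-matrix from [znormToBaseline()].
#' @param geneSet character set of genes.
#' @param groupSamples column ids of the group's samples.
#' @return scalar `Z_tg`.
#' @export
groupSetScore <- function(z, geneSet, groupSamples) {
  g <- intersect(geneSet, rownames(z))
  if (!length(g)) stop("gene set has no member in the z-matrix")
  mean(z[g, groupSamples, drop = FALSE])
}

#' Cell-type composition shift test with a resampling null
#'
#' For each cell-type gene set and each non-baseline experimental group,
#' the observed mean z-score `Z_tg` is referred to the distribution of the
#' same statistic over `nRandom` random gene sets of identical size drawn
#' without replacement from the full gene universe. A Gaussian is fitted to
#' the null scores (their normality is checked with a Shapiro test at
#' alpha 0.01 and reported), the empirical p-value comes from its CDF
#' (two-sided by default), and Bonferroni correction runs over
#' (#groups - baselines) x (#sets) tests as constructed in the call. The
#' same random draws are reused across groups for a given set size.
#'
#' @param z z-matrix from [znormToBaseline()].
#' @param geneSets named list of cell-type gene sets.
#' @param groups named list: group label -> column ids of its samples.
#' @param baseline name(s) of the baseline group(s) to exclude from
#'   testing.
#' @param nRandom number of random sets (>= 1000; default 10000).
#' @param seed integer seed.
#' @param sided `"two"` (default) or `"one"` (upper tail).
#' @return DataFrame with `set`, `group`, `z_tg`, `null_mean`, `null_sd`,
#'   `p_empirical`, `p_bonf`, `null_normal_p`.
#' @export
shiftTest <- function(z, geneSets, groups, baseline, nRandom = 10000,
                      seed = 1, sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(nRandom >= 1000)
  genes <- rownames(z)
  testGroups <- setdiff(names(groups), baseline)
  if (!length(testGroups)) stop("no non-baseline groups to test")

  # per-gene, per-group mean z; Z_tg is then a mean over set genes because
  # each gene contributes the same number of samples within a group
  gm <- vapply(names(groups), function(g) {
    idx <- groups[[g]]
    rowMeans(z[, idx, drop = FALSE])
  }, numeric(nrow(z)))

  setSizes <- vapply(geneSets, function(s)
    length(intersect(s, genes)), integer(1))
  if (any(setSizes == 0)) stop("gene set(s) with no member in the z-matrix")
  if (max(setSizes) * 2 > length(genes))
    stop("universe must be at least twice the largest set size")

  nullBySize <- list()
  for (k in sort(unique(setSizes))) {
    draws <- .withSeed(.subSeed(seed, paste0("draws_", k)), {
      matrix(unlist(lapply(seq_len(nRandom), function(i)
        sample.int(length(genes), k))), nrow = nRandom, byrow = TRUE)
    })
    # null Z_rtg for every group at once: mean over drawn genes of gm
    nullBySize[[as.character(k)]] <- vapply(names(groups), function(g) {
      v <- gm[, g]
      rowMeans(matrix(v[draws], nrow = nRandom))
    }, numeric(nRandom))
  }

  nTests <- length(testGroups) * length(geneSets)
  rows <- list()
  for (s in names(geneSets)) {
    gs <- intersect(geneSets[[s]], genes)
    nulls <- nullBySize[[as.character(length(gs))]]
    for (g in testGroups) {
      obs <- mean(gm[gs, g])
      nm <- mean(nulls[, g]); nsd <- stats::sd(nulls[, g])
      if (nsd == 0) stop("degenerate null (sd 0) for set ", s)
      zz <- (obs - nm) / nsd
      p <- if (sided == "two") 2 * stats::pnorm(-abs(zz)) else
        stats::pnorm(zz, lower.tail = FALSE)
      sw <- stats::shapiro.test(
        if (nRandom > 5000) nulls[seq_len(5000), g] else nulls[, g])$p.value
      rows[[length(rows) + 1]] <-
        DataFrame(set = s, group = g, z_tg = obs, null_mean = nm,
                  null_sd = nsd, p_empirical = p,
                  p_bonf = min(1, p * nTests), null_normal_p = sw)
    }
  }
  do.call(rbind, rows)
}
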