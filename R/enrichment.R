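#' @include AllClasses.R utils.R bulkDE.R
NULL

#' Build nested GWAS risk-gene sets from an association table
#'
#' For each p-value cutoff `c`, the set is every universe gene whose
#' (Bonferroni-adjusted) association p-value satisfies `pMar < c`; sets are
#' nested by construction. Duplicate gene entries are resolved by keeping
#' the minimum `pMar`; an optional two-column orthology map (`source`,
#' `target`) translates gene ids before thresholding.
#'
#' @param gwas data.frame/DataFrame with columns `gene` and `pMar`.
#' @param cutoffs ascending numeric cutoffs (default the classic ladder
#'   5e-8 ... 5e-2).
#' @param universe character; genes present in the expression data.
#' @param orthology optional data.frame with columns `source`, `target`.
#' @return named list of character vectors, one per cutoff, names
#'   `"pMar<5e-08"` etc.; set sizes are attached as `attr(, "sizes")`.
#' @export
buildGwasSets <- function(gwas, cutoffs = c(5e-8, 5e-6, 1e-4, 1e-3, 1e-2,
                                            5e-2),
                          universe, orthology = NULL) {
  if (!length(universe)) stop("empty universe")
  stopifnot(!is.unsorted(cutoffs))
  gene <- as.character(gwas$gene)
  p <- as.numeric(gwas$pMar)
  if (!is.null(orthology)) {
    idx <- match(gene, orthology$source)
    gene <- ifelse(is.na(idx), gene, as.character(orthology$target[idx]))
  }
  p <- tapply(p, gene, min)         # duplicates -> minimum pMar
  gene <- names(p)
  keep <- gene %in% universe
  gene <- gene[keep]; p <- p[keep]
  sets <- lapply(cutoffs, function(ct) gene[p < ct])
  names(sets) <- paste0("pMar<", format(cutoffs, scientific = TRUE,
                                        trim = TRUE))
  attr(sets, "sizes") <- vapply(sets, length, integer(1))
  sets
}

# Core weighted running-sum statistic. ranked: metrics sorted most-up to
# most-down; hit: logical membership aligned with the ranking.
.runningSum <- function(metric, hit, weightExponent = 1) {
  nH <- sum(hit)
  n <- length(metric)
  if (nH == 0) stop("gene set has no member in the ranking")
  if (nH == n) stop("gene set covers all ranked genes (miss denominator 0)")
  w <- abs(metric[hit])^weightExponent
  if (sum(w) == 0) {
    warning("all-zero hit weights; falling back to uniform increments")
    w <- rep(1, nH)
  }
  inc <- numeric(n)
  inc[hit] <- w / sum(w)
  inc[!hit] <- -1 / (n - nH)
  cumsum(inc)
}

#' Weighted running-sum enrichment score
#'
#' The preranked gene-set statistic: walking down the ranking, set members
#' increment the running sum by their |metric|^p (normalized to total 1
#' over members) and non-members decrement it by 1/(N - N_H); the
#' enrichment score is the running-sum value of maximal absolute deviation
#' from zero, signed. Genes in the set but absent from the ranking are
#' dropped before scoring.
#'
#' @param ranked DataFrame/data.frame with `gene` and `metric`, sorted
#'   most-up to most-down (see [signedRanking()]).
#' @param geneSet character vector of member genes.
#' @param weightExponent weight exponent p (default 1, the classic
#'   "weighted" statistic).
#' @return list with `es` (in `[-1, 1]`) and `runningSum` (length N).
#' @export
enrichmentScore <- function(ranked, geneSet, weightExponent = 1) {
  hit <- ranked$gene %in% geneSet
  rs <- .runningSum(ranked$metric, hit, weightExponent)
  list(es = rs[which.max(abs(rs))], runningSum = rs)
}

#' Preranked enrichment test with a gene-set resampling null
#'
#' For each set, the observed enrichment score is compared with scores of
#' random same-size gene sets drawn from the ranking. The p-value uses the
#' add-one estimator over same-sign null draws,
#' `p = (1 + #\{|ES_null| >= |ES|, same sign\}) / (1 + #\{same sign\})`,
#' and the normalized score is `nes = es / mean(|ES_null| same sign)`.
#' BY adjustment is applied across all sets tested in the call; when
#' results from several contrasts belong to one family, rbind them first
#' and re-adjust with [adjustBY()].
#'
#' @param ranked DataFrame with `gene` and `metric`, sorted.
#' @param geneSets named list of gene sets.
#' @param nResamples number of null draws (>= 100; default 1000).
#' @param seed integer seed for the null draws.
#' @param weightExponent weight exponent p.
#' @return DataFrame with `set`, `size`, `es`, `nes`, `p`, `p_adj`.
#' @export
prerankedTest <- function(ranked, geneSets, nResamples = 1000, seed = 1,
                          weightExponent = 1) {
  stopifnot(nResamples >= 100)
  n <- nrow(ranked)
  metric <- ranked$metric
  rows <- lapply(names(geneSets), function(nm) {
    inRank <- intersect(geneSets[[nm]], ranked$gene)
    k <- length(inRank)
    obs <- enrichmentScore(ranked, inRank, weightExponent)$es
    nullEs <- .withSeed(.subSeed(seed, paste0("null_", nm)), {
      vapply(seq_len(nResamples), function(i) {
        hit <- logical(n)
        hit[sample.int(n, k)] <- TRUE
        rs <- .runningSum(metric, hit, weightExponent)
        rs[which.max(abs(rs))]
      }, numeric(1))
    })
    same <- nullEs[sign(nullEs) == sign(obs)]
    if (!length(same)) {
      warning("no same-sign null draws for set ", nm, "; p reported as 1")
      p <- 1
      nes <- NA_real_
    } else {
      p <- (1 + sum(abs(same) >= abs(obs))) / (1 + length(same))
      nes <- obs / mean(abs(same))
    }
    DataFrame(set = nm, size = k, es = obs, nes = nes, p = p)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- adjustBY(res$p)
  res
}

#' One-sided Fisher-style set overlap test with log-odds ratio
#'
#' Upper-tail hypergeometric p-value for the overlap of two sets within a
#' common universe (the one-sided Fisher exact test for enrichment), plus a
#' log2 odds ratio with Haldane's 0.5 correction applied only when some
#' 2x2 cell is zero.
#'
#' @param setA,setB character vectors, both subsets of `universe`.
#' @param universe character background.
#' @return list with `lor` (log2 odds ratio), `p` (one-sided upper), and
#'   the 2x2 `table`.
#' @export
fisherSetEnrichment <- function(setA, setB, universe) {
  if (!length(universe)) stop("empty universe")
  setA <- unique(intersect(setA, universe))
  setB <- unique(intersect(setB, universe))
  N <- length(unique(universe))
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  cc <- length(setB) - a
  d <- N - a - b - cc
  h <- if (min(a, b, cc, d) == 0) 0.5 else 0
  lor <- log2(((a + h) * (d + h)) / ((b + h) * (cc + h)))
  p <- stats::phyper(a - 1, length(setA), N - length(setA), length(setB),
                     lower.tail = FALSE)
  list(lor = lor, p = p,
       table = matrix(c(a, b, cc, d), 2, 2,
                      dimnames = list(c("inA", "outA"), c("inB", "outB"))))
}

#' Overlap of every module with every gene set, BY-adjusted
#'
#' Applies [fisherSetEnrichment()] to each (module, set) pair and
#' BY-adjusts across all pairs tested.
#'
#' @param partition a [ModulePartition-class].
#' @param geneSets named list of gene sets.
#' @param universe character background (defaults to all partitioned
#'   genes).
#' @return DataFrame with `module`, `set`, `overlap`, `lor`, `p`, `p_adj`.
#' @export
moduleEnrichmentTable <- function(partition, geneSets,
                                  universe = names(moduleLabels(partition))) {
  labels <- moduleLabels(partition)
  mods <- setdiff(unique(labels), "unassigned")
  rows <- list()
  for (m in mods) {
    mg <- names(labels)[labels == m]
    for (s in names(geneSets)) {
      fe <- fisherSetEnrichment(mg, geneSets[[s]], universe)
      rows[[length(rows) + 1]] <-
        DataFrame(module = m, set = s, overlap = fe$table["inA", "inB"],
                  lor = fe$lor, p = fe$p)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- adjustBY(res$p)
  res
}
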