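test_that("low-count filter applies the mean/sample rule exactly", {
  # 3 genes x 12 samples: only gene B exceeds mean 5 in >= 10 samples
  cts <- rbind(A = rep(0L, 12),
               B = c(rep(10L, 11), 0L),
               C = c(rep(10L, 9), 0L, 0L, 0L))
  colnames(cts) <- sprintf("s%02d", 1:12)
  sam <- data.frame(strain = "APP",
                    genotype = rep(c("WT", "TG"), each = 6),
                    age = rep(c("4M", "10M"), times = 6))
  be <- BulkExperiment(cts, sam)
  expect_identical(rownames(filterLowCounts(be, 5, 10)), "B")
  expect_identical(rownames(filterLowCounts(be, 0, 0)), c("A", "B", "C"))
  expect_warning(filterLowCounts(be, 1e9, 12), "no genes")
})

test_that("log-CPM matches its closed form and cancels library size", {
  base <- c(0L, 10L, 90L, 150L)
  cts <- cbind(s1 = base, s2 = 2L * base,
               matrix(rep(base, 6), 4, 6,
                      dimnames = list(NULL, sprintf("s%d", 3:8))))
  rownames(cts) <- c("a", "b", "c", "d")
  sam <- data.frame(strain = "APP",
                    genotype = rep(c("WT", "TG"), each = 4),
                    age = rep(c("4M", "10M"), times = 4))
  be <- normalizeLogCpm(BulkExperiment(cts, sam), pseudocount = 0.5)
  lc <- SummarizedExperiment::assay(be, "logcpm")
  expect_equal(lc["a", "s1"], log2(0.5))
  expect_equal(lc["b", "s1"], log2(1e6 * 10 / 250 + 0.5))
  # s2 doubles s1's counts: library-size cancellation up to the pseudocount
  expect_equal(lc["c", "s1"], lc["c", "s2"], tolerance = 1e-3)
  expect_equal(lc["d", "s1"], lc["d", "s2"], tolerance = 1e-3)
})

test_that("normalizeLogCpm recovers CPM through the inverse transform", {
  sim <- simulateBulkCounts(nGenes = 40, nPerGroup = 2, programSize = 4,
                            seed = 1)
  be <- normalizeLogCpm(sim$experiment, pseudocount = 0.5)
  v <- SummarizedExperiment::assay(be, "logcpm")
  cts <- SummarizedExperiment::assay(be, "counts")
  lib <- S4Vectors::metadata(be)$librarySizes
  cpmBack <- 2^v - 0.5
  expect_equal(cpmBack, t(t(cts) / lib) * 1e6, tolerance = 1e-9)
  # zero library size errors with the sample named
  cts0 <- cts; cts0[, 1] <- 0L
  be0 <- BulkExperiment(cts0, SummarizedExperiment::colData(sim$experiment))
  expect_error(normalizeLogCpm(be0), colnames(cts0)[1])
})

test_that("residualization removes orthogonal batch structure exactly", {
  gm <- matrix(c(1, 2, 3, 4), 1, 4,
               dimnames = list("g1", c("WT4", "WT10", "TG4", "TG10")))
  be <- toyBulk(gm, nPerGroup = 4)
  # no nuisance effect: output == input
  cd <- SummarizedExperiment::colData(be)
  cd$batch <- factor(rep(c("b1", "b2"), times = 8))
  cd$concentration <- 50
  SummarizedExperiment::colData(be) <- cd
  out <- residualizeCovariates(be, nuisance = "batch")
  expect_lt(max(abs(SummarizedExperiment::assay(out, "logcpm") -
                      SummarizedExperiment::assay(be, "logcpm"))), 1e-8)

  # +2 offset on batch b2, balanced within groups -> removed exactly
  be2 <- be
  x <- SummarizedExperiment::assay(be2, "logcpm")
  x[, cd$batch == "b2"] <- x[, cd$batch == "b2"] + 2
  SummarizedExperiment::assay(be2, "logcpm") <- x
  out2 <- residualizeCovariates(be2, nuisance = "batch")
  x2 <- SummarizedExperiment::assay(out2, "logcpm")
  for (g in unique(cd$group)) {
    i <- cd$group == g
    expect_lt(diff(range(x2[1, i])), 1e-8)
  }

  # batch perfectly confounded with genotype -> rank-deficiency error
  cd$batch <- factor(cd$genotype)
  SummarizedExperiment::colData(be) <- cd
  expect_error(residualizeCovariates(be, nuisance = "batch"), "aliased")
})

test_that("2x2 contrasts match their closed forms", {
  gm1 <- matrix(c(0, 0, 0, 3), 1, 4,
                dimnames = list("g1", c("WT4", "WT10", "TG4", "TG10")))
  de <- suppressWarnings(fitTwoByTwo(toyBulk(gm1, nPerGroup = 3), "fig1c"))
  lfc <- setNames(de$lfc, de$contrast)
  expect_equal(lfc[["age"]], 1.5)
  expect_equal(lfc[["genotype"]], 1.5)
  expect_equal(lfc[["age_x_genotype"]], 3)
  deC <- suppressWarnings(fitTwoByTwo(toyBulk(gm1, nPerGroup = 3), "classical"))
  expect_equal(deC$lfc[deC$contrast == "age_x_genotype"], 3)

  # the case that distinguishes the two interaction styles
  gm2 <- matrix(c(0, 1, 1, 2), 1, 4,
                dimnames = list("g1", c("WT4", "WT10", "TG4", "TG10")))
  d1 <- suppressWarnings(fitTwoByTwo(toyBulk(gm2, nPerGroup = 3), "fig1c"))
  d2 <- suppressWarnings(fitTwoByTwo(toyBulk(gm2, nPerGroup = 3), "classical"))
  expect_equal(d1$lfc[d1$contrast == "age_x_genotype"], 2 - 2 / 3)
  expect_equal(d2$lfc[d2$contrast == "age_x_genotype"], 0)

  # identical groups with symmetric residual noise: estimate 0, p = 1
  gm3 <- matrix(c(5, 5, 5, 5), 1, 4,
                dimnames = list("g1", c("WT4", "WT10", "TG4", "TG10")))
  d3 <- fitTwoByTwo(toyBulk(gm3, nPerGroup = 4, noise = symNoise))
  expect_true(all(d3$lfc == 0))
  expect_true(all(d3$p == 1))

  # empty design cell errors
  be <- toyBulk(gm1, nPerGroup = 3)
  expect_error(fitTwoByTwo(be[, 4:12]), "cell")
})

test_that("contrast estimates agree with a group-means oracle", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      gm <- matrix(rnorm(8 * 4), 8, 4,
                   dimnames = list(sprintf("g%d", 1:8),
                                   c("WT4", "WT10", "TG4", "TG10")))
      be <- toyBulk(gm, nPerGroup = 3, noise = function(n) rnorm(n, 0, 0.3))
      x <- SummarizedExperiment::assay(be, "logcpm")
      cd <- SummarizedExperiment::colData(be)
      m <- vapply(c("WT.4M", "WT.10M", "TG.4M", "TG.10M"), function(g) {
        parts <- strsplit(g, ".", fixed = TRUE)[[1]]
        rowMeans(x[, cd$genotype == parts[1] & cd$age == parts[2],
                   drop = FALSE])
      }, numeric(nrow(x)))
      de <- fitTwoByTwo(be, "fig1c")
      expect_equal(de$lfc[de$contrast == "age"],
                   unname((m[, 2] + m[, 4]) / 2 - (m[, 1] + m[, 3]) / 2),
                   tolerance = 1e-10)
      expect_equal(de$lfc[de$contrast == "genotype"],
                   unname((m[, 3] + m[, 4]) / 2 - (m[, 1] + m[, 2]) / 2),
                   tolerance = 1e-10)
      expect_equal(de$lfc[de$contrast == "age_x_genotype"],
                   unname(m[, 4] - rowMeans(m[, 1:3])), tolerance = 1e-10)
    }
  })
})

test_that("BY adjustment matches the harmonic closed form", {
  expect_equal(adjustBY(c(0.01, 0.02, 0.03)), rep(0.03 * (1 + 1/2 + 1/3), 3))
  expect_equal(adjustBY(0.2), 0.2)
  expect_equal(adjustBY(c(1, 1, 1)), c(1, 1, 1))
  expect_error(adjustBY(c(0.5, 1.2)), "0, 1")
  # random vectors against the explicit step-up construction
  withr::with_seed(1, {
    for (rep in 1:10) {
      p <- runif(50)
      m <- length(p)
      cm <- sum(1 / seq_len(m))
      o <- order(p)
      stepped <- pmin(1, cummin(rev(p[o] * cm * m / seq_len(m))))
      manual <- numeric(m)
      manual[o] <- rev(stepped)
      expect_equal(adjustBY(p), manual, tolerance = 1e-12)
    }
  })
})

test_that("signed ranking metric follows sign(lfc) * -log10(p)", {
  de <- S4Vectors::DataFrame(
    gene = c("a", "b", "c"), contrast = "age_x_genotype",
    lfc = c(1.5, -1.5, 2), p = c(0.01, 0.01, 1),
    p_adj = c(0.02, 0.02, 1))
  r <- signedRanking(de)
  m <- setNames(r$metric, r$gene)
  expect_equal(m[["a"]], 2)
  expect_equal(m[["b"]], -2)
  expect_equal(m[["c"]], 0)
  expect_identical(r$gene[1], "a")  # sorted most-up first
  de$p[1] <- 0
  expect_warning(signedRanking(de), "floored")
})

test_that("rank correlation uses the either-significant union", {
  mkRes <- function(metrics, padj) S4Vectors::DataFrame(
    gene = sprintf("g%d", seq_along(metrics)), contrast = "age_x_genotype",
    lfc = metrics, p = 0.01, p_adj = padj, metric = metrics)
  a <- mkRes(c(1, 2, 3, 4, 5), rep(0.01, 5))
  expect_equal(rankCorrelation(a, a)$rho, 1)
  b <- mkRes(c(5, 4, 3, 2, 1), rep(0.01, 5))
  expect_equal(rankCorrelation(a, b)$rho, -1)
  b2 <- mkRes(c(1, 3, 2, 5, 4), rep(0.01, 5))
  expect_equal(rankCorrelation(a, b2)$rho, 0.8)
  # non-significant genes are excluded from the subset
  a3 <- mkRes(c(1, 2, 3, 4, 5), c(0.01, 0.01, 0.01, 1, 1))
  b3 <- mkRes(c(1, 2, 3, -9, -9), c(0.01, 0.01, 0.01, 1, 1))
  expect_equal(rankCorrelation(a3, b3)$n, 3)
  expect_error(rankCorrelation(mkRes(1:2, rep(0.01, 2)),
                               mkRes(1:2, rep(0.01, 2))), "fewer than 3")
})
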