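test_that("QC applies the read, mito and doublet rules in order", {
  ce <- toyCells(totals = c(500, 800, 40000, 900),
                 mitoFracs = c(0.01, 0.06, 0.01, 0.01))
  out <- qcFilter(ce, minCellsPerGene = 0)
  expect_identical(colnames(out$experiment), "c04")
  expect_identical(out$cellReport$reason,
                   c("low_reads", "high_mito", "doublet_cap", NA))
  # each failed cell has exactly one primary reason
  expect_true(all(is.na(out$cellReport$reason) == out$cellReport$pass))

  # thresholds at their extremes are the identity
  all <- qcFilter(ce, minReads = 0, maxMito = 1, doubletCap = Inf,
                  minCellsPerGene = 0)
  expect_identical(dim(all$experiment), dim(ce))

  expect_error(qcFilter(toyCells(100, 0.5)), "survive")
})

test_that("QC gene rule and order-independence", {
  sf <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("G1", c("HM", "ARM")))
  sim <- simulateCellCounts(genes = sprintf("g%03d", 1:150),
                            stateFractions = sf, nCellsPerGroup = 300,
                            seed = 3)
  out <- qcFilter(sim$experiment, minCellsPerGene = 100)
  det <- Matrix::rowSums(
    SummarizedExperiment::assay(out$experiment, "counts") > 0)
  expect_true(all(det >= 100))
  noGeneFilter <- qcFilter(sim$experiment, minCellsPerGene = 0)
  expect_identical(nrow(noGeneFilter$experiment), nrow(sim$experiment))

  perm <- withr::with_seed(1, sample(ncol(sim$experiment)))
  outP <- qcFilter(sim$experiment[, perm], minCellsPerGene = 100)
  expect_setequal(colnames(outP$experiment), colnames(out$experiment))
  expect_identical(sort(rownames(outP$experiment)),
                   sort(rownames(out$experiment)))
})

test_that("cell normalization matches ln(1 + scale * umi / total)", {
  m <- Matrix::Matrix(matrix(c(0, 100, 9900, 0, 300, 29700), 3, 2,
                             dimnames = list(c("a", "b", "mt-1"),
                                             c("c1", "c2"))), sparse = TRUE)
  ce <- CellExperiment(m, groups = c("G1", "G1"), mitoGenes = "mt-1")
  nce <- normalizeCells(ce, scale = 1e4)
  lc <- SummarizedExperiment::assay(nce, "logcounts")
  expect_equal(lc["a", "c1"], 0)
  expect_equal(lc["b", "c1"], log(101))
  # cell 2 is cell 1 times 3: normalized values identical
  expect_equal(as.numeric(lc[, "c1"]), as.numeric(lc[, "c2"]),
               tolerance = 1e-12)
})

test_that("module score separates signal from bin-matched controls", {
  # constructed fixture: marker genes at 2.0, everything else at 0.5 in a
  # single expression bin -> score exactly 1.5
  nG <- 60; nC <- 20
  x <- matrix(0.5, nG, nC, dimnames = list(sprintf("g%02d", 1:nG),
                                           sprintf("c%02d", 1:nC)))
  markers <- sprintf("g%02d", 1:10)
  x[markers, ] <- 2
  ce <- CellExperiment(matrix(1L, nG, nC, dimnames = dimnames(x)),
                       groups = rep("G1", nC))
  SummarizedExperiment::assay(ce, "logcounts") <- x
  sc <- moduleScore(ce, markers, nBins = 1, seed = 1)
  expect_equal(sc, rep(1.5, nC))

  # self-control: a random set scored against its own population ~ 0
  withr::with_seed(5, {
    y <- matrix(abs(rnorm(1000 * 30)), 1000, 30,
                dimnames = list(sprintf("g%04d", 1:1000),
                                sprintf("c%02d", 1:30)))
    ceY <- CellExperiment(matrix(1L, 1000, 30, dimnames = dimnames(y)),
                          groups = rep("G1", 30))
    SummarizedExperiment::assay(ceY, "logcounts") <- y
    set <- sample(rownames(y), 100)
  })
  s <- moduleScore(ceY, set, nBins = 1, seed = 2)
  expect_lt(abs(mean(s)), 0.05)

  # determinism under a fixed seed
  expect_identical(moduleScore(ceY, set, seed = 7),
                   moduleScore(ceY, set, seed = 7))
})

test_that("state assignment is argmax with lexicographic ties", {
  sc <- rbind(c1 = c(HM = 0.9, ARM = 0.1),
              c2 = c(HM = 0.2, ARM = 0.7),
              c3 = c(HM = 0.5, ARM = 0.5))
  a <- assignStates(sc, groups = rep("G1", 3))
  expect_identical(unname(a$states), c("HM", "ARM", "ARM"))  # tie -> ARM
  expect_equal(sum(a$fractions), 1)
  expect_error(assignStates(sc[, "ARM", drop = FALSE], rep("G1", 3)),
               "2 state")
  expect_error(assignStates(sc, rep("G1", 3), homeostatic = "HOM"),
               "homeostatic")
})

test_that("planted state fractions are recovered from scored cells", {
  sf <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("G1", c("HM", "ARM")))
  sim <- simulateCellCounts(genes = sprintf("g%03d", 1:300),
                            stateFractions = sf, nCellsPerGroup = 1000,
                            lowQualityFrac = 0, doubletFrac = 0, seed = 6)
  ce <- normalizeCells(sim$experiment)
  sigs <- S4Vectors::metadata(ce)$stateSignatures
  scores <- vapply(names(sigs), function(nm)
    moduleScore(ce, sigs[[nm]], seed = 11), numeric(ncol(ce)))
  rownames(scores) <- colnames(ce)
  a <- assignStates(scores, SummarizedExperiment::colData(ce)$group)
  expect_lt(abs(a$fractions["G1", "ARM"] - 0.5), 0.05)
})

test_that("state DE matches exact rank-sum enumeration and the lfc rule", {
  # complete separation with 4 vs 4 cells: exact two-sided p = 2/70
  x <- matrix(0, 2, 8, dimnames = list(c("g1", "g2"),
                                       sprintf("c%d", 1:8)))
  x["g1", ] <- c(5, 6, 7, 8, 1, 2, 3, 4)
  x["g2", ] <- c(1, 2, 1.5, 1.2, 1.1, 1.9, 1.4, 1.6)
  ce <- CellExperiment(matrix(1L, 2, 8, dimnames = dimnames(x)),
                       groups = rep("G1", 8))
  SummarizedExperiment::assay(ce, "logcounts") <- x
  res <- stateDE(ce, sprintf("c%d", 1:4), sprintf("c%d", 5:8))
  expect_equal(res$p[res$gene == "g1"], 2 / 70, tolerance = 1e-12)

  # exact enumeration oracle for n <= 8 per side
  withr::with_seed(3, {
    for (nA in c(3, 5)) for (nB in c(4, 8)) {
      a <- rnorm(nA); b <- rnorm(nB, 1)
      W <- sum(rank(c(a, b))[seq_len(nA)]) - nA * (nA + 1) / 2
      combos <- utils::combn(nA + nB, nA)
      vals <- c(a, b)
      nullW <- apply(combos, 2, function(idx)
        sum(rank(vals)[idx]) - nA * (nA + 1) / 2)
      pEnum <- min(1, 2 * min(mean(nullW <= W), mean(nullW >= W)))
      xx <- rbind(g = c(a, b))
      colnames(xx) <- sprintf("c%d", seq_len(nA + nB))
      cc <- CellExperiment(matrix(1L, 1, nA + nB, dimnames = dimnames(xx)),
                           groups = rep("G1", nA + nB))
      SummarizedExperiment::assay(cc, "logcounts") <- xx
      r <- stateDE(cc, sprintf("c%d", seq_len(nA)),
                   sprintf("c%d", nA + seq_len(nB)))
      expect_equal(r$p, pEnum, tolerance = 1e-12)
    }
  })
})

test_that("state DE significance applies strict thresholds", {
  withr::with_seed(8, {
    x <- matrix(abs(rnorm(20 * 40, 1)), 20, 40,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("c%02d", 1:40)))
  })
  ce <- CellExperiment(matrix(1L, 20, 40, dimnames = dimnames(x)),
                       groups = rep("G1", 40))
  SummarizedExperiment::assay(ce, "logcounts") <- x
  # identical groups: nothing significant
  res <- stateDE(ce, sprintf("c%02d", 1:20), sprintf("c%02d", 1:20))
  expect_true(all(!res$significant))

  # lfc exactly at the threshold does not pass the strict inequality
  # engineer |lfc| == 0.2 exactly: groupA constant a, groupB constant 1,
  # with expm1(a) + 1 = exp(0.2) * (expm1(1) + 1)
  xb <- matrix(1, 1, 12, dimnames = list("g1", sprintf("c%02d", 1:12)))
  xb[1, 1:6] <- 0.2 + log(expm1(1) + 1)
  ceb <- CellExperiment(matrix(1L, 1, 12, dimnames = dimnames(xb)),
                        groups = rep("G1", 12))
  SummarizedExperiment::assay(ceb, "logcounts") <- xb
  rb <- stateDE(ceb, sprintf("c%02d", 1:6), sprintf("c%02d", 7:12))
  expect_equal(abs(rb$lfc), 0.2, tolerance = 1e-12)
  expect_false(any(rb$significant))
})

test_that("cross-result concordance is Spearman on the significant union", {
  mk <- function(lfc, sig) S4Vectors::DataFrame(
    gene = sprintf("g%d", seq_along(lfc)), lfc = lfc,
    p = 0.001, p_adj = 0.001, significant = sig)
  a <- mk(c(1, 2, 3, 4), rep(TRUE, 4))
  expect_equal(stateDeConcordance(a, a)$rho, 1)
  b <- mk(c(4, 3, 2, 1), rep(TRUE, 4))
  expect_equal(stateDeConcordance(a, b)$rho, -1)
  expect_error(stateDeConcordance(mk(1:2, c(TRUE, TRUE)),
                                  mk(1:2, c(TRUE, TRUE))), "3 shared")
})
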