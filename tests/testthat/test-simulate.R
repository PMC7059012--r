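test_that("bulk generator is deterministic and validates parameters", {
  a <- simulateBulkCounts(nGenes = 120, nPerGroup = 3, programSize = 12,
                          seed = 7)
  b <- simulateBulkCounts(nGenes = 120, nPerGroup = 3, programSize = 12,
                          seed = 7)
  expect_identical(SummarizedExperiment::assay(a$experiment, "counts"),
                   SummarizedExperiment::assay(b$experiment, "counts"))
  expect_error(simulateBulkCounts(nGenes = 0), "positive")
  expect_error(simulateBulkCounts(nGenes = 10, programSize = 20), "exceed")
  expect_error(simulateBulkCounts(dispersion = 0), "dispersion")
  # every DE gene appears in the emitted matrix
  expect_true(all(deGenes(a$truth) %in% rownames(a$experiment)))
})

test_that("null bulk generation carries no interaction effect", {
  sim <- simulateBulkCounts(nGenes = 400, nPerGroup = 12, programSize = 40,
                            interactionLfc = 0, dispersion = 0.1, seed = 3)
  expect_length(deGenes(sim$truth), 0)
  cts <- SummarizedExperiment::assay(sim$experiment, "counts")
  cd <- SummarizedExperiment::colData(sim$experiment)
  tgt <- cd$strain == "APP" & cd$genotype == "TG" & cd$age == "10M"
  cpm <- t(t(cts) / colSums(cts))
  ratio <- rowMeans(cpm[, tgt]) / rowMeans(cpm[, !tgt])
  # mean ratio across genes ~ 1 within NB sampling error at n = 12
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("planted interaction LFC is recovered at low dispersion", {
  # small program so the 4-fold effect barely perturbs library composition
  sim <- simulateBulkCounts(nGenes = 500, nPerGroup = 50, programSize = 5,
                            interactionLfc = 2, dispersion = 1e-3, seed = 5)
  cts <- SummarizedExperiment::assay(sim$experiment, "counts")
  cd <- SummarizedExperiment::colData(sim$experiment)
  tgt <- cd$strain == "APP" & cd$genotype == "TG" & cd$age == "10M"
  ref <- cd$strain == "APP" & !(cd$genotype == "TG" & cd$age == "10M")
  cpm <- t(t(cts) / colSums(cts))
  est <- log2(rowMeans(cpm[deGenes(sim$truth), tgt]) /
                rowMeans(cpm[deGenes(sim$truth), ref]))
  expect_true(all(abs(est - 2) < 0.1))
})

test_that("GWAS table enrichment strength controls program overlap", {
  base <- simulateBulkCounts(nGenes = 1000, nPerGroup = 3,
                             programSize = 100, seed = 11)
  prog <- names(moduleAssignment(base$truth))[
    moduleAssignment(base$truth) == "program"]

  forced <- simulateGwasTable(base$truth, nRisk = 50, enrichmentStrength = 1,
                              seed = 2)
  expect_true(all(names(forced$riskGenes) %in% prog))
  expect_true(all(forced$table$pMar > 0 & forced$table$pMar <= 1))

  # enrichmentStrength = 0: overlap ~ hypergeometric expectation over seeds
  ov <- vapply(1:20, function(s) {
    g <- simulateGwasTable(base$truth, nRisk = 100,
                           enrichmentStrength = 0, seed = s)
    length(intersect(names(g$riskGenes), prog))
  }, numeric(1))
  expectHyper <- 100 * 100 / 1000
  se <- sqrt(20) * sqrt(expectHyper)  # generous bound on the seed mean
  expect_lt(abs(mean(ov) - expectHyper), 3 * sqrt(expectHyper * 0.9 / 20) + 1)

  expect_error(simulateGwasTable(GroundTruth()), "universe")
  expect_error(simulateGwasTable(base$truth, enrichmentStrength = 2), "0, 1")
})

test_that("nested GWAS sets are monotone in the cutoff", {
  base <- simulateBulkCounts(nGenes = 500, nPerGroup = 3, programSize = 50,
                             seed = 1)
  g <- simulateGwasTable(base$truth, nRisk = 80, seed = 1)
  sets <- buildGwasSets(g$table, cutoffs = c(1e-5, 1e-3, 5e-2),
                        universe = names(moduleAssignment(base$truth)))
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("marker sets honor sizes, disjointness and the universe", {
  genes <- sprintf("g%05d", 1:4000)
  sets <- simulateMarkerSets(genes, seed = 2)
  expect_length(sets, 7)
  expect_identical(unname(vapply(sets, length, integer(1))),
                   c(701L, 364L, 239L, 435L, 452L, 352L, 483L))
  all <- unlist(sets)
  expect_identical(anyDuplicated(all), 0L)
  expect_true(all(all %in% genes))
  expect_identical(intersect(sets$microglia, genes), sets$microglia)
  expect_error(simulateMarkerSets(genes[1:100], sizes = c(a = 60L, b = 60L)),
               "oversubscribe")
})

test_that("single-cell generator plants state fractions and QC structure", {
  sf <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("G1", c("HM", "ARM")))
  sim <- simulateCellCounts(genes = sprintf("g%03d", 1:200),
                            stateFractions = sf, nCellsPerGroup = 1000,
                            lowQualityFrac = 0, doubletFrac = 0, seed = 4)
  st <- SummarizedExperiment::colData(sim$experiment)$trueState
  nArm <- sum(st == "ARM")
  # binomial 99% interval around 500
  expect_true(abs(nArm - 500) < qnorm(0.995) * sqrt(1000 * 0.25))

  sim2 <- simulateCellCounts(genes = sprintf("g%03d", 1:200),
                             stateFractions = sf, nCellsPerGroup = 1000,
                             lowQualityFrac = 0, doubletFrac = 0, seed = 4)
  expect_identical(st, SummarizedExperiment::colData(sim2$experiment)$trueState)

  sf0 <- matrix(c(1, 0), 1, 2, dimnames = list("G1", c("HM", "ARM")))
  sim3 <- simulateCellCounts(genes = sprintf("g%03d", 1:100),
                             stateFractions = sf0, nCellsPerGroup = 200,
                             seed = 1)
  expect_identical(
    sum(SummarizedExperiment::colData(sim3$experiment)$trueState == "ARM"),
    0L)

  bad <- matrix(c(0.6, 0.6), 1, 2, dimnames = list("G1", c("HM", "ARM")))
  expect_error(simulateCellCounts(stateFractions = bad), "sum to 1")
})

test_that("ground-truth invariants hold for the full study scenario", {
  study <- simulateStudy(seed = 2, nGenes = 600, nPerGroup = 3,
                         programSize = 60, nRisk = 60, nCellsPerGroup = 50,
                         nScGenes = 300)
  tr <- study$truth
  expect_true(all(abs(rowSums(stateFractions(tr)) - 1) < 1e-12))
  expect_true(all(microgliosisFactor(tr) >= 1))
  expect_true(all(deGenes(tr) %in% rownames(study$bulk)))
  expect_true(all(study$markerSets$microglia %in% study$programGenes))
  # identity markers are not forced into the risk-gene draw
  forcedRisk <- intersect(names(riskGenes(tr)), study$programGenes)
  expect_lt(length(intersect(forcedRisk, study$markerSets$microglia)),
            0.2 * length(forcedRisk))
  expect_s4_class(study$cells, "CellExperiment")
})

test_that("tsv / gmt / mtx round trips preserve the data", {
  dir <- withr::local_tempdir()
  sim <- simulateBulkCounts(nGenes = 50, nPerGroup = 2, programSize = 5,
                            seed = 1)
  writeBulkTsv(sim$experiment, file.path(dir, "counts.tsv"),
               file.path(dir, "samples.tsv"))
  be2 <- readBulkTsv(file.path(dir, "counts.tsv"),
                     file.path(dir, "samples.tsv"))
  expect_equal(SummarizedExperiment::assay(be2, "counts"),
               SummarizedExperiment::assay(sim$experiment, "counts"))

  sets <- list(a = c("g1", "g2"), b = c("g3"))
  writeGmt(sets, file.path(dir, "sets.gmt"))
  expect_identical(readGmt(file.path(dir, "sets.gmt")), sets)

  sf <- matrix(c(0.7, 0.3), 1, 2, dimnames = list("G1", c("HM", "ARM")))
  sc <- simulateCellCounts(genes = sprintf("g%03d", 1:100),
                           stateFractions = sf, nCellsPerGroup = 30,
                           seed = 9)
  write10x(sc$experiment, file.path(dir, "tenx"))
  ce2 <- read10x(file.path(dir, "tenx"),
                 mitoGenes = S4Vectors::metadata(sc$experiment)$mitoGenes)
  expect_equal(as.matrix(SummarizedExperiment::assay(ce2, "counts")),
               as.matrix(SummarizedExperiment::assay(sc$experiment,
                                                     "counts")))
})
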