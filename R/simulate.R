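#' @include AllClasses.R utils.R
NULL

.groupLabel <- function(strain, genotype, age)
  paste0(strain, tolower(genotype), "_", age)

#' Simulate bulk RNA-seq counts for a two-strain 2x2 factorial design
#'
#' Draws negative-binomial counts for 8 experimental groups (2 strains x
#' \{4M, 10M\} x \{WT, TG\}) with gene-level means drawn log-normally, a
#' single dispersion parameter, per-sample library-size factors, and
#' multiplicative library-prep batch factors as the technical nuisance
#' structure. A designated "program" of genes carries the configured
#' interaction effect (log2 units) only in the amyloid-like strain's TG-10M
#' cell, emulating an amyloid-responsive gene program; the tau-like strain
#' receives no program effect. Optional per-gene, per-group multipliers
#' (`extraEffects`) inject cell-type composition shifts such as
#' microgliosis.
#'
#' @param nGenes number of genes (>= `programSize`).
#' @param nPerGroup samples per experimental group (default 12).
#' @param programSize number of program genes.
#' @param interactionLfc true log2 interaction effect for program genes;
#'   scalar or vector of length `programSize`. Use 0 for a null dataset.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); must be > 0.
#' @param seed integer master seed; all sub-steps derive named streams.
#' @param strains two strain labels; `programStrain` names the amyloid-like
#'   one that receives the program effect.
#' @param programStrain strain carrying the interaction effect.
#' @param librarySize expected total counts per sample.
#' @param libSdLog log-sd of the per-sample library-size factor.
#' @param nBatches number of library-prep batches (assigned cyclically).
#' @param batchSdLog log-sd of the multiplicative per-batch factor.
#' @param extraEffects optional gene-by-group multiplier matrix (rownames =
#'   gene ids, colnames = group labels as `"APPtg_10M"`); entries default 1.
#' @param geneNames optional explicit gene ids.
#' @param programGenes optional explicit program gene ids (otherwise
#'   sampled).
#' @return list with `experiment` ([BulkExperiment-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' sim <- simulateBulkCounts(nGenes = 100, nPerGroup = 3, programSize = 10,
#'                           seed = 1)
#' sim$experiment
#' @export
simulateBulkCounts <- function(nGenes = 2000, nPerGroup = 12,
                               programSize = 200, interactionLfc = 2,
                               dispersion = 0.1, seed = 1,
                               strains = c("APP", "TAU"),
                               programStrain = "APP", librarySize = 1e6,
                               libSdLog = 0.2, nBatches = 4,
                               batchSdLog = 0.1, extraEffects = NULL,
                               geneNames = NULL, programGenes = NULL) {
  if (nGenes < 1 || nPerGroup < 2 || programSize < 1)
    stop("nGenes, nPerGroup and programSize must be positive ",
         "(nPerGroup >= 2)")
  if (nGenes < programSize) stop("programSize must not exceed nGenes")
  if (dispersion <= 0) stop("dispersion must be > 0")
  genes <- if (is.null(geneNames)) sprintf("g%05d", seq_len(nGenes)) else
    geneNames
  stopifnot(length(genes) == nGenes)

  design <- expand.grid(genotype = c("WT", "TG"), age = c("4M", "10M"),
                        strain = strains, stringsAsFactors = FALSE)
  samples <- design[rep(seq_len(nrow(design)), each = nPerGroup), ]
  samples$group <- .groupLabel(samples$strain, samples$genotype, samples$age)
  samples$batch <- factor(rep_len(paste0("b", seq_len(nBatches)),
                                  nrow(samples)))
  rownames(samples) <- sprintf("%s_%02d", samples$group,
                               sequence(rep(nPerGroup, nrow(design))))
  n <- nrow(samples)

  rel <- .withSeed(.subSeed(seed, "baseMeans"),
                   stats::rlnorm(nGenes, meanlog = 0, sdlog = 1.5))
  baseMeans <- rel / sum(rel) * librarySize
  samples$concentration <- .withSeed(.subSeed(seed, "concentration"),
                                     stats::runif(n, 20, 100))
  libFac <- .withSeed(.subSeed(seed, "libSizes"),
                      stats::rlnorm(n, 0, libSdLog))
  batchFac <- .withSeed(.subSeed(seed, "batchFactors"),
                        stats::rlnorm(nBatches, 0, batchSdLog))
  sizeFac <- libFac * batchFac[as.integer(samples$batch)]

  if (is.null(programGenes))
    programGenes <- .withSeed(.subSeed(seed, "program"),
                              sample(genes, programSize))
  else {
    stopifnot(all(programGenes %in% genes))
    programSize <- length(programGenes)
  }
  lfcVec <- rep_len(interactionLfc, programSize)
  names(lfcVec) <- programGenes

  logEff <- matrix(0, nGenes, n, dimnames = list(genes, rownames(samples)))
  target <- samples$strain == programStrain & samples$genotype == "TG" &
    samples$age == "10M"
  logEff[programGenes, target] <- lfcVec
  eff <- 2^logEff
  if (!is.null(extraEffects)) {
    gi <- intersect(rownames(extraEffects), genes)
    for (grp in intersect(colnames(extraEffects), unique(samples$group))) {
      cols <- samples$group == grp
      eff[gi, cols] <- eff[gi, cols] * extraEffects[gi, grp]
    }
  }

  mu <- baseMeans * eff * rep(sizeFac, each = nGenes)
  counts <- .withSeed(.subSeed(seed, "counts"),
                      matrix(stats::rnbinom(nGenes * n, mu = mu,
                                            size = 1 / dispersion),
                             nGenes, n,
                             dimnames = list(genes, rownames(samples))))
  be <- BulkExperiment(counts, samples)
  assignment <- stats::setNames(rep("background", nGenes), genes)
  assignment[programGenes] <- "program"
  truth <- GroundTruth(deGenes = programGenes[lfcVec != 0],
                       interactionLfc = lfcVec,
                       moduleAssignment = assignment, seed = seed)
  list(experiment = be, truth = truth)
}

#' Simulate a GWAS gene association table
#'
#' Assigns per-gene adjusted association p-values so that nested risk-gene
#' sets can be built by thresholding. A fraction `enrichmentStrength` of the
#' `nRisk` risk genes is forced into the planted program; the remainder is
#' drawn uniformly from the whole universe, so `enrichmentStrength = 0`
#' recovers hypergeometric (chance) overlap with the program. Risk genes
#' receive p-values log-uniform on (1e-8, 0.05); all other emitted genes
#' receive p-values uniform on (0.05, 1].
#'
#' @param truth a [GroundTruth-class] carrying the program assignment.
#' @param nRisk number of risk genes.
#' @param nBackground number of additional non-risk genes to emit.
#' @param enrichmentStrength fraction of risk genes drawn from the program,
#'   in `[0, 1]`.
#' @param excludeFromForced genes never used for the forced in-program
#'   draw (e.g. cell-identity markers that are not risk genes); they stay
#'   eligible for the uniform remainder.
#' @param seed integer seed.
#' @return list with `table` (DataFrame: `gene`, `pMar`) and `riskGenes`
#'   (named numeric of true association p-values).
#' @export
simulateGwasTable <- function(truth, nRisk = 200, nBackground = 800,
                              enrichmentStrength = 0.5,
                              excludeFromForced = NULL, seed = 1) {
  if (enrichmentStrength < 0 || enrichmentStrength > 1)
    stop("enrichmentStrength must lie in [0, 1]")
  assignment <- moduleAssignment(truth)
  if (!length(assignment)) stop("ground truth carries no gene universe")
  genes <- names(assignment)
  program <- genes[assignment == "program"]
  program <- setdiff(program, excludeFromForced)
  kProg <- round(enrichmentStrength * nRisk)
  if (kProg > length(program))
    stop("program too small for the requested enrichmentStrength")
  risk <- .withSeed(.subSeed(seed, "riskGenes"), {
    forced <- sample(program, kProg)
    free <- sample(setdiff(genes, forced), nRisk - kProg)
    c(forced, free)
  })
  pRisk <- .withSeed(.subSeed(seed, "riskP"),
                     10^stats::runif(nRisk, log10(1e-8), log10(0.05)))
  names(pRisk) <- risk
  nBg <- min(nBackground, length(genes) - nRisk)
  bg <- .withSeed(.subSeed(seed, "backgroundGenes"),
                  sample(setdiff(genes, risk), nBg))
  pBg <- .withSeed(.subSeed(seed, "backgroundP"),
                   stats::runif(nBg, 0.05, 1))
  tab <- DataFrame(gene = c(risk, bg), pMar = c(pRisk, pBg))
  tab <- tab[order(tab$pMar), ]
  list(table = tab, riskGenes = pRisk)
}

#' Simulate cell-type marker gene sets
#'
#' Draws pairwise-disjoint marker sets for the major brain cell types from
#' a gene universe. Default sizes are the classic hippocampus panel sizes
#' (pyramidal neurons 701, interneurons 364, astrocytes 239, microglia 435,
#' oligodendrocytes 452, endothelial 352, ependymal 483) rescaled to the
#' universe when it is smaller than the ~16k genes those sizes assume.
#'
#' @param genes character gene universe.
#' @param sizes named integer vector of set sizes; `NULL` picks the default
#'   panel (rescaled if needed).
#' @param seed integer seed.
#' @param pools optional named list giving, for specific sets, the candidate
#'   gene pool to draw from (still kept disjoint from other sets).
#' @return named list of character vectors (GMT-style collection).
#' @export
simulateMarkerSets <- function(genes, sizes = NULL, seed = 1, pools = list()) {
  paperSizes <- c(pyramidal_neurons = 701, interneurons = 364,
                  astrocytes = 239, microglia = 435,
                  oligodendrocytes = 452, endothelial = 352, ependymal = 483)
  if (is.null(sizes)) {
    sizes <- paperSizes
    if (sum(sizes) > length(genes)) {
      # small universe: shrink the panel, preserving its proportions (the
      # full-size panel covers ~19% of a ~16k-gene transcriptome)
      sc <- 0.19 * length(genes) / sum(sizes)
      sizes <- pmax(10L, as.integer(round(sizes * sc)))
      names(sizes) <- names(paperSizes)
    }
  }
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("sizes must be named")
  if (sum(sizes) > length(genes))
    stop("marker sets oversubscribe the gene universe")
  .withSeed(.subSeed(seed, "markerSets"), {
    used <- character()
    sets <- list()
    for (nm in names(sizes)) {
      pool <- if (!is.null(pools[[nm]])) intersect(pools[[nm]], genes) else
        genes
      pool <- setdiff(pool, used)
      if (length(pool) < sizes[[nm]])
        stop("pool for set '", nm, "' oversubscribed")
      sets[[nm]] <- sample(pool, sizes[[nm]])
      used <- c(used, sets[[nm]])
    }
    sets
  })
}

.defaultStateFractions <- function(strains = c("APP", "TAU")) {
  # ARM fractions: drastic age increase in the amyloid model (26.5% -> 56.7%),
  # mild in the tau model (14.9% -> 21.3%), 4-10% in wild types.
  arm <- c(0.05, 0.10, 0.265, 0.567, 0.04, 0.09, 0.149, 0.213)
  grp <- c(.groupLabel(strains[1], c("WT", "WT", "TG", "TG"),
                       c("4M", "10M", "4M", "10M")),
           .groupLabel(strains[2], c("WT", "WT", "TG", "TG"),
                       c("4M", "10M", "4M", "10M")))
  m <- cbind(HM = 1 - arm, ARM = arm)
  rownames(m) <- grp
  m
}

#' Simulate single-cell microglia UMI counts with planted state structure
#'
#' Cells are drawn from a per-group multinomial mixture over transcriptional
#' states (default: homeostatic HM and activated ARM, with ARM fractions
#' rising steeply with age in the amyloid-like strain and mildly in the
#' tau-like strain). Each state's signature genes are elevated
#' `signatureFold`-fold in cells of that state. A designated 5% slice of the
#' gene universe acts as mitochondrial genes; a small fraction of
#' low-quality cells (too few reads, excessive mitochondrial content, or
#' doublet-scale totals) is injected so QC filtering is exercisable.
#'
#' @param genes gene universe (character); default `sprintf("g%05d", 1:1000)`.
#' @param stateFractions group-by-state fraction matrix with rows summing to
#'   1; `NULL` uses the default table described above.
#' @param nCellsPerGroup cells per experimental group.
#' @param stateSignatures named list of signature gene sets, one per state
#'   (names must match `colnames(stateFractions)`); `NULL` samples disjoint
#'   signatures of size `signatureSize` from the non-mitochondrial universe.
#' @param signatureSize,signatureFold signature size and fold elevation.
#' @param meanDepth,depthSdLog log-normal parameters of per-cell total UMIs.
#' @param mitoGenes explicit mitochondrial gene ids; `NULL` designates the
#'   last 5% slice of `genes`.
#' @param lowQualityFrac fraction of cells made to fail read/mito QC.
#' @param doubletFrac fraction of cells given doublet-scale totals.
#' @param seed integer seed.
#' @return list with `experiment` ([CellExperiment-class], true state labels
#'   in `colData()$trueState`) and `truth` ([GroundTruth-class] carrying the
#'   state-fraction table).
#' @export
simulateCellCounts <- function(genes = sprintf("g%05d", seq_len(1000)),
                               stateFractions = NULL, nCellsPerGroup = 800,
                               stateSignatures = NULL, signatureSize = 50,
                               signatureFold = 8, meanDepth = 2000,
                               depthSdLog = 0.35, mitoGenes = NULL,
                               lowQualityFrac = 0.04, doubletFrac = 0.005,
                               seed = 1) {
  if (is.null(stateFractions)) stateFractions <- .defaultStateFractions()
  if (any(abs(rowSums(stateFractions) - 1) > 1e-9))
    stop("state fractions must sum to 1 per group (tol 1e-9)")
  states <- colnames(stateFractions)
  groups <- rownames(stateFractions)
  nGenes <- length(genes)
  if (is.null(mitoGenes)) {
    nMito <- max(1L, as.integer(round(0.05 * nGenes)))
    mitoGenes <- genes[(nGenes - nMito + 1):nGenes]
  }
  if (is.null(stateSignatures)) {
    pool <- setdiff(genes, mitoGenes)
    signatureSize <- min(signatureSize, floor(length(pool) / length(states)))
    stateSignatures <- .withSeed(.subSeed(seed, "signatures"), {
      out <- list()
      for (st in states) {
        out[[st]] <- sample(pool, signatureSize)
        pool <- setdiff(pool, out[[st]])
      }
      out
    })
  }
  stopifnot(all(states %in% names(stateSignatures)))

  baseW <- .withSeed(.subSeed(seed, "cellBaseWeights"),
                     stats::rlnorm(nGenes, 0, 1))
  names(baseW) <- genes
  stateW <- sapply(states, function(st) {
    w <- baseW
    w[intersect(stateSignatures[[st]], genes)] <-
      w[intersect(stateSignatures[[st]], genes)] * signatureFold
    w
  })

  nCells <- nCellsPerGroup * length(groups)
  cellGroup <- rep(groups, each = nCellsPerGroup)
  cellState <- .withSeed(.subSeed(seed, "cellStates"), {
    unlist(lapply(groups, function(g)
      sample(states, nCellsPerGroup, replace = TRUE,
             prob = stateFractions[g, ])))
  })
  depth <- .withSeed(.subSeed(seed, "cellDepth"),
                     pmax(760, round(stats::rlnorm(nCells, log(meanDepth),
                                                   depthSdLog))))
  qcFlags <- .withSeed(.subSeed(seed, "qcInjection"), {
    u <- stats::runif(nCells)
    flag <- rep("ok", nCells)
    flag[u < lowQualityFrac / 2] <- "low_reads"
    flag[u >= lowQualityFrac / 2 & u < lowQualityFrac] <- "high_mito"
    flag[u >= lowQualityFrac & u < lowQualityFrac + doubletFrac] <- "doublet"
    flag
  })
  depth[qcFlags == "low_reads"] <- .withSeed(
    .subSeed(seed, "lowDepth"),
    round(stats::runif(sum(qcFlags == "low_reads"), 100, 740)))
  depth[qcFlags == "doublet"] <- .withSeed(
    .subSeed(seed, "doubletDepth"),
    round(stats::runif(sum(qcFlags == "doublet"), 31000, 40000)))

  counts <- .withSeed(.subSeed(seed, "cellCounts"), {
    m <- matrix(0L, nGenes, nCells)
    mitoIdx <- match(mitoGenes, genes)
    for (i in seq_len(nCells)) {
      w <- stateW[, cellState[i]]
      if (qcFlags[i] == "high_mito") w[mitoIdx] <- w[mitoIdx] * 12
      m[, i] <- stats::rmultinom(1, depth[i], prob = w)
    }
    m
  })
  dimnames(counts) <- list(genes,
                           sprintf("%s_c%05d", cellGroup, seq_len(nCells)))
  counts <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  ce <- CellExperiment(counts, groups = cellGroup, mitoGenes = mitoGenes,
                       trueState = cellState)
  truth <- GroundTruth(stateFractions = stateFractions, seed = seed)
  metadata(ce)$stateSignatures <- stateSignatures
  list(experiment = ce, truth = truth)
}

#' Simulate the full two-strain study with coherent ground truth
#'
#' Wires the individual generators into one scenario mirroring the study
#' design the package targets: an amyloid-responsive program of genes
#' upregulated only in the amyloid-like strain's aged transgenics, a
#' microglia marker set contained in that program (the program is a
#' microglial activation module), neuronal loss in the tau-like strain's
#' transgenics, a GWAS table whose risk genes preferentially hit the
#' program, and single-cell microglia whose activated-state fraction rises
#' with amyloid pathology.
#'
#' @param seed master seed.
#' @param nGenes bulk gene universe size.
#' @param nPerGroup samples per bulk group.
#' @param programSize program (true module) size.
#' @param interactionLfc true interaction effect (log2) for program genes.
#' @param dispersion NB dispersion.
#' @param enrichmentStrength fraction of risk genes inside the program.
#' @param nRisk number of GWAS risk genes.
#' @param nCellsPerGroup single-cell group size.
#' @param nScGenes single-cell gene universe size (subset of bulk genes).
#' @param microgliosis named per-group microglial abundance multipliers
#'   (>= 1, baseline 1); `NULL` uses the default (1.3/1.8 in amyloid TG at
#'   4M/10M, 1.05/1.15 in tau TG, 1 in WT).
#' @param withSingleCell set `FALSE` to skip the single-cell arm (bulk-only
#'   studies; `cells` and `stateSignatures` come back `NULL`).
#' @param ... further arguments passed to [simulateBulkCounts()].
#' @return list with components `bulk`, `cells`, `gwas` (DataFrame),
#'   `markerSets`, `stateSignatures`, `truth` (merged [GroundTruth-class])
#'   and `programGenes`.
#' @export
simulateStudy <- function(seed = 1, nGenes = 2000, nPerGroup = 12,
                          programSize = 200, interactionLfc = 2,
                          dispersion = 0.1, enrichmentStrength = 0.5,
                          nRisk = 200, nCellsPerGroup = 800, nScGenes = 1000,
                          microgliosis = NULL, withSingleCell = TRUE, ...) {
  genes <- sprintf("g%05d", seq_len(nGenes))
  programGenes <- .withSeed(.subSeed(seed, "studyProgram"),
                            sample(genes, programSize))

  sizes <- c(pyramidal_neurons = 701, interneurons = 364, astrocytes = 239,
             microglia = 435, oligodendrocytes = 452, endothelial = 352,
             ependymal = 483)
  sizes <- pmax(10L, as.integer(round(sizes * nGenes / 15824)))
  names(sizes) <- c("pyramidal_neurons", "interneurons", "astrocytes",
                    "microglia", "oligodendrocytes", "endothelial",
                    "ependymal")
  # the program is a microglial activation module: the microglia identity
  # markers sit inside it (so the recovered module is marker-enriched) and
  # carry the abundance (microgliosis) response in both strains, while GWAS
  # risk genes are drawn from the program's activation arm only - identity
  # markers are homeostatic genes, not risk genes
  nonProgram <- setdiff(genes, programGenes)
  pools <- stats::setNames(rep(list(nonProgram), length(sizes)),
                           names(sizes))
  pools$microglia <- programGenes
  markerSets <- simulateMarkerSets(
    genes, sizes = sizes, seed = .subSeed(seed, "studyMarkers"),
    pools = pools)

  groups <- rownames(.defaultStateFractions())
  if (is.null(microgliosis)) {
    microgliosis <- stats::setNames(rep(1, length(groups)), groups)
    microgliosis[c("APPtg_4M", "APPtg_10M")] <- c(1.3, 1.8)
    microgliosis[c("TAUtg_4M", "TAUtg_10M")] <- c(1.05, 1.15)
  }
  neuronalLoss <- stats::setNames(rep(1, length(groups)), groups)
  neuronalLoss[c("TAUtg_4M", "TAUtg_10M")] <- c(0.9, 0.8)

  extra <- matrix(1, nGenes, length(groups),
                  dimnames = list(genes, groups))
  extra[markerSets$microglia, ] <-
    rep(microgliosis, each = length(markerSets$microglia))
  extra[markerSets$pyramidal_neurons, ] <-
    rep(neuronalLoss, each = length(markerSets$pyramidal_neurons))

  bulkSim <- simulateBulkCounts(nGenes = nGenes, nPerGroup = nPerGroup,
                                programSize = programSize,
                                interactionLfc = interactionLfc,
                                dispersion = dispersion, seed = seed,
                                extraEffects = extra, geneNames = genes,
                                programGenes = programGenes, ...)
  gwasSim <- simulateGwasTable(bulkSim$truth, nRisk = nRisk,
                               enrichmentStrength = enrichmentStrength,
                               excludeFromForced = markerSets$microglia,
                               seed = seed)

  cells <- NULL; sigs <- NULL
  sf <- .defaultStateFractions()
  if (withSingleCell) {
    scGenes <- unique(c(programGenes, markerSets$microglia,
                        .withSeed(.subSeed(seed, "scFiller"),
                                  sample(setdiff(genes, programGenes),
                                         max(0, nScGenes - programSize)))))
    nMito <- max(1L, round(0.05 * length(scGenes)))
    mito <- setdiff(scGenes, programGenes)
    mito <- utils::tail(mito, nMito)
    hmPool <- setdiff(scGenes, c(programGenes, mito))
    armPool <- setdiff(programGenes, markerSets$microglia)
    sigs <- .withSeed(.subSeed(seed, "studySignatures"), list(
      HM = sample(hmPool, min(50, length(hmPool))),
      ARM = sample(armPool, min(50, length(armPool)))))
    cellSim <- simulateCellCounts(genes = scGenes,
                                  nCellsPerGroup = nCellsPerGroup,
                                  stateSignatures = sigs, mitoGenes = mito,
                                  seed = .subSeed(seed, "studyCells"))
    cells <- cellSim$experiment
    sf <- stateFractions(cellSim$truth)
  }

  truth <- GroundTruth(
    deGenes = deGenes(bulkSim$truth),
    interactionLfc = interactionLfc(bulkSim$truth),
    riskGenes = gwasSim$riskGenes,
    moduleAssignment = moduleAssignment(bulkSim$truth),
    stateFractions = sf,
    microgliosisFactor = microgliosis, seed = seed)

  list(bulk = bulkSim$experiment, cells = cells,
       gwas = gwasSim$table, markerSets = markerSets,
       stateSignatures = sigs, truth = truth, programGenes = programGenes)
}

#' Simulate a gene panel whose bulk means follow the microgliosis model
#'
#' Constructs per-group observed means for a panel of genes as
#' `M_g * (f_HM(g) mu_HM + f_ARM+(g) mu_ARM+)` plus Gaussian noise with sd a
#' fraction of each gene's predicted range (a "microglial" panel), or as
#' group profiles statistically independent of the prediction (a matched
#' negative-control panel).
#'
#' @param M named microgliosis index per group (baseline 1).
#' @param fractions group-by-state matrix with columns `HM` and `ARM`
#'   summing to 1.
#' @param nGenes panel size.
#' @param noiseFrac noise sd as a fraction of the per-gene predicted range.
#' @param microglial if `FALSE`, observed means are independent of the
#'   prediction.
#' @param armFoldRange range of ARM/HM expression fold changes per gene.
#' @param seed integer seed.
#' @return list with matrices `observed`, `muHM`, `muARM` (gene x group) and
#'   `predicted`.
#' @export
simulateDeconvolutionPanel <- function(M, fractions, nGenes = 20,
                                       noiseFrac = 0.1, microglial = TRUE,
                                       armFoldRange = c(2, 5), seed = 1) {
  groups <- names(M)
  stopifnot(!is.null(groups), all(groups %in% rownames(fractions)))
  .withSeed(.subSeed(seed, "deconvPanel"), {
    base <- stats::rlnorm(nGenes, log(2), 0.4)
    fold <- stats::runif(nGenes, armFoldRange[1], armFoldRange[2])
    genes <- sprintf("panel%03d", seq_len(nGenes))
    muHM <- matrix(base, nGenes, length(groups),
                   dimnames = list(genes, groups))
    muARM <- muHM * fold
    pred <- muHM * rep(fractions[groups, "HM"], each = nGenes) +
      muARM * rep(fractions[groups, "ARM"], each = nGenes)
    pred <- pred * rep(M, each = nGenes)
    rng <- apply(pred, 1, function(x) diff(range(x)))
    if (microglial) {
      obs <- pred + matrix(stats::rnorm(length(pred)), nGenes) *
        (noiseFrac * rng)
    } else {
      obs <- matrix(stats::rlnorm(length(pred), log(2), 0.5), nGenes,
                    length(groups), dimnames = dimnames(pred))
    }
    dimnames(obs) <- dimnames(pred)
    list(observed = obs, muHM = muHM, muARM = muARM, predicted = pred)
  })
}
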