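#' @include AllClasses.R simulate.R bulkDE.R enrichment.R coexpression.R
#' @include intersection.R shift.R singleCell.R deconvolution.R
NULL

#' Default pipeline configuration
#'
#' All stage parameters with their canonical defaults: low-count filter
#' mean 5 exceeded in a 10/96 fraction of samples, BY adjustment at
#' alpha 0.05 throughout the bulk analyses (Bonferroni in the single-cell
#' test), GWAS cutoffs from 5e-8 to 5e-2, 1,000 enrichment resamples,
#' 10,000 shift-null draws, the TG-10M-versus-rest interaction contrast,
#' and two-sided shift testing.
#'
#' @param seed master seed; every seed-consuming stage derives a named
#'   sub-seed from it.
#' @return a nested list; override any entry before passing to
#'   [runPipeline()].
#' @export
pipelineConfig <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(nGenes = 2000, nPerGroup = 12, programSize = 200,
                    interactionLfc = 2, dispersion = 0.1,
                    enrichmentStrength = 0.5, nRisk = 200,
                    nCellsPerGroup = 800, nScGenes = 1000),
    filter = list(minMean = 5, minSamplesFraction = 10 / 96),
    de = list(contrastStyle = "fig1c", alpha = 0.05, pseudocount = 0.5),
    enrichment = list(cutoffs = c(5e-8, 5e-6, 1e-4, 1e-3, 1e-2, 5e-2),
                      nResamples = 1000),
    network = list(powers = 1:10, r2Target = 0.9, minModuleSize = 30,
                   cutHeight = 0.95, mergeCorr = 0.75,
                   kmeThreshold = 0.5),
    shift = list(nRandom = 10000, sided = "two"),
    singleCell = list(minReads = 750, maxMito = 0.05, doubletCap = 30000,
                      minCellsPerGene = 100, lfcThreshold = 0.2,
                      alpha = 0.05),
    deconvolution = list(r2Threshold = 0.67, alpha = 0.05),
    prioritize = list(cutoff = 1e-3))
}

.groupsOf <- function(be, strain = NULL) {
  cd <- colData(be)
  sel <- if (is.null(strain)) rep(TRUE, ncol(be)) else cd$strain == strain
  split(colnames(be)[sel], cd$group[sel])
}

#' Prioritize candidate genes by exact multi-set intersection
#'
#' The convergence filter: genes that are simultaneously (i) members of the
#' target co-expression module, (ii) GWAS risk genes below the chosen
#' cutoff, and (iii) significantly differentially expressed in the
#' interaction contrast (`p_adj < alpha`). The exact intersection test is
#' run with the full analysis universe as background.
#'
#' @param de DataFrame from [fitTwoByTwo()].
#' @param partition a [ModulePartition-class].
#' @param gwasSets nested sets from [buildGwasSets()].
#' @param targetModule module name to intersect.
#' @param cutoff name or numeric cutoff selecting one GWAS set.
#' @param alpha DE significance level.
#' @return list with `genes` (the prioritized list, possibly empty) and
#'   `test` (an [IntersectionTest-class]).
#' @export
prioritizeGenes <- function(de, partition, gwasSets, targetModule,
                            cutoff = 1e-3, alpha = 0.05) {
  labels <- moduleLabels(partition)
  if (!targetModule %in% labels) stop("module not found: ", targetModule)
  if (is.numeric(cutoff)) {
    nm <- paste0("pMar<", format(cutoff, scientific = TRUE, trim = TRUE))
    if (!nm %in% names(gwasSets)) stop("cutoff not among configured sets")
    gset <- gwasSets[[nm]]
  } else gset <- gwasSets[[cutoff]]
  d <- de[de$contrast == "age_x_genotype", ]
  sig <- d$gene[d$p_adj < alpha]
  modGenes <- names(labels)[labels == targetModule]
  universe <- unique(d$gene)
  genes <- Reduce(intersect, list(modGenes, intersect(gset, universe), sig))
  test <- intersectionTest(length(universe),
                           c(length(intersect(modGenes, universe)),
                             length(intersect(gset, universe)),
                             length(intersect(sig, universe))),
                           length(genes))
  list(genes = genes, test = test)
}

#' Run the full analysis pipeline on synthetic or supplied data
#'
#' Executes the stages in dependency order: data synthesis (or intake),
#' bulk filtering/normalization/residualization, per-strain 2x2
#' differential expression, nested GWAS-set preranked enrichment,
#' co-expression module detection with marker/GWAS annotation, exact
#' multi-set prioritization, cell-type shift testing, single-cell QC /
#' state assignment / activated-versus-homeostatic DE, and the
#' microgliosis-aware deconvolution of the prioritized genes. Identical
#' config (including seed) yields identical results.
#'
#' @param config list from [pipelineConfig()] (edit entries to override);
#'   supply `data` to skip simulation.
#' @param data optional list with elements `bulk`, `cells`, `gwas`,
#'   `markerSets`, `stateSignatures` (and optionally `truth`) as produced
#'   by [simulateStudy()].
#' @param outputDir optional directory; when given, stage tables are
#'   written as TSV/JSON artifacts.
#' @return a report list with per-stage results: `de` (per strain),
#'   `deCounts`, `rankCorrelation`, `enrichment`, `modules` (per strain),
#'   `moduleEnrichment`, `prioritized`, `shift`, `stateFractions`,
#'   `stateDe`, `stateConcordance`, `deconvolution`, plus `truth` when
#'   simulated.
#' @export
runPipeline <- function(config = pipelineConfig(), data = NULL,
                        outputDir = NULL) {
  seed <- config$seed
  if (is.null(data)) {
    sim <- config$simulate
    data <- simulateStudy(seed = seed, nGenes = sim$nGenes,
                          nPerGroup = sim$nPerGroup,
                          programSize = sim$programSize,
                          interactionLfc = sim$interactionLfc,
                          dispersion = sim$dispersion,
                          enrichmentStrength = sim$enrichmentStrength,
                          nRisk = sim$nRisk,
                          nCellsPerGroup = sim$nCellsPerGroup,
                          nScGenes = sim$nScGenes)
  }
  be <- data$bulk
  strains <- unique(colData(be)$strain)

  # --- bulk preprocessing ---------------------------------------------
  minSamples <- max(1, round(config$filter$minSamplesFraction * ncol(be)))
  be <- filterLowCounts(be, config$filter$minMean, minSamples)
  be <- normalizeLogCpm(be, config$de$pseudocount)
  be <- residualizeCovariates(be)
  universe <- rownames(be)

  # --- per-strain DE, ranking, enrichment, network --------------------
  gwasSets <- buildGwasSets(data$gwas, config$enrichment$cutoffs, universe)
  de <- list(); ranks <- list(); enr <- list(); modules <- list()
  modEnrich <- list()
  for (st in strains) {
    sub <- be[, colData(be)$strain == st]
    x <- assay(sub, "logcpm")
    de[[st]] <- fitTwoByTwo(sub, config$de$contrastStyle)
    ranks[[st]] <- signedRanking(de[[st]])
    enr[[st]] <- prerankedTest(ranks[[st]], gwasSets,
                               config$enrichment$nResamples,
                               seed = .subSeed(seed, paste0("gsea_", st)))
    sp <- pickSoftPower(x, config$network$powers, config$network$r2Target)
    tom <- adjacencyTom(x, sp$beta)
    part <- detectModules(tom, x, config$network$minModuleSize,
                          config$network$cutHeight,
                          config$network$mergeCorr,
                          config$network$kmeThreshold)
    part@fitTable <- sp$fitTable
    modules[[st]] <- part
    if (length(moduleSizes(part)))
      modEnrich[[st]] <- moduleEnrichmentTable(
        part, c(data$markerSets, gwasSets), universe)
  }
  deCounts <- do.call(rbind, lapply(strains, function(st) {
    d <- de[[st]]
    do.call(rbind, lapply(unique(d$contrast), function(cn) {
      dd <- d[d$contrast == cn, ]
      sig <- dd$p_adj < config$de$alpha
      DataFrame(strain = st, contrast = cn,
                up = sum(sig & dd$lfc > 0), down = sum(sig & dd$lfc < 0),
                nonsig = sum(!sig), total = nrow(dd))
    }))
  }))
  rankCor <- tryCatch(
    rankCorrelation(de[[strains[1]]], de[[strains[2]]],
                    alpha = config$de$alpha),
    error = function(e) NULL)

  # --- prioritization (amyloid-like strain) ---------------------------
  ampStrain <- strains[1]
  target <- NULL; prioritized <- NULL
  if (length(moduleSizes(modules[[ampStrain]]))) {
    # target module: the one most enriched for microglia markers
    me <- modEnrich[[ampStrain]]
    mg <- me[me$set == "microglia", ]
    target <- mg$module[which.min(mg$p)]
    prioritized <- prioritizeGenes(de[[ampStrain]], modules[[ampStrain]],
                                   gwasSets, target,
                                   config$prioritize$cutoff,
                                   config$de$alpha)
  }

  # --- cell-type shift -------------------------------------------------
  shift <- list()
  for (st in strains) {
    sub <- be[, colData(be)$strain == st]
    x <- assay(sub, "logcpm")
    grps <- .groupsOf(sub)
    baseline <- grep("wt_4M$", names(grps), value = TRUE)
    z <- znormToBaseline(x, unlist(grps[baseline]))
    shift[[st]] <- shiftTest(z, data$markerSets, grps, baseline,
                             config$shift$nRandom,
                             seed = .subSeed(seed, paste0("shift_", st)),
                             sided = config$shift$sided)
  }

  # --- single-cell states ----------------------------------------------
  sc <- config$singleCell
  qc <- qcFilter(data$cells, sc$minReads, sc$maxMito, sc$doubletCap,
                 sc$minCellsPerGene)
  cells <- normalizeCells(qc$experiment)
  sigs <- data$stateSignatures
  scores <- vapply(names(sigs), function(nm)
    moduleScore(cells, sigs[[nm]],
                seed = .subSeed(seed, paste0("score_", nm))),
    numeric(ncol(cells)))
  rownames(scores) <- colnames(cells)
  assignment <- assignStates(scores, colData(cells)$group,
                             homeostatic = "HM")
  stateDeRes <- list(); conc <- NULL
  groupsByStrain <- split(colnames(cells),
                          sub("(wt|tg)_.*$", "", colData(cells)$group))
  for (st in names(groupsByStrain)) {
    isSt <- colnames(cells) %in% groupsByStrain[[st]]
    arm <- colnames(cells)[isSt & assignment$states != "HM"]
    hm <- colnames(cells)[isSt & assignment$states == "HM"]
    if (length(arm) >= 3 && length(hm) >= 3)
      stateDeRes[[st]] <- stateDE(cells, arm, hm, sc$lfcThreshold,
                                  sc$alpha)
  }
  if (length(stateDeRes) == 2)
    conc <- tryCatch(stateDeConcordance(stateDeRes[[1]], stateDeRes[[2]]),
                     error = function(e) NULL)

  # --- deconvolution of prioritized genes -----------------------------
  deconv <- NULL
  if (!is.null(prioritized) && length(prioritized$genes)) {
    panel <- intersect(prioritized$genes, rownames(cells))
    grps <- .groupsOf(be)
    grps <- grps[names(grps) %in% rownames(assignment$fractions)]
    baseline <- grep("APPwt_4M", names(grps), value = TRUE)
    if (length(panel) >= 2 && length(grps) >= 4) {
      x <- assay(be, "logcpm")
      z <- znormToBaseline(x, unlist(grps[baseline]))
      frac <- assignment$fractions
      colnames(frac)[colnames(frac) != "HM"] <- "ARM"
      deconv <- deconvolveGenes(cells, assignment$states, be, z,
                                data$markerSets$microglia, frac, panel,
                                grps,
                                r2Threshold = config$deconvolution$r2Threshold,
                                alpha = config$deconvolution$alpha)
    }
  }

  report <- list(config = config, de = de, deCounts = deCounts,
                 rankCorrelation = rankCor, enrichment = enr,
                 gwasSetSizes = attr(gwasSets, "sizes"),
                 modules = modules, moduleEnrichment = modEnrich,
                 targetModule = target, prioritized = prioritized,
                 shift = shift, qc = qc["cellReport"],
                 stateFractions = assignment$fractions,
                 stateDe = stateDeRes, stateConcordance = conc,
                 deconvolution = deconv, truth = data$truth)
  if (!is.null(outputDir)) .writeReport(report, outputDir)
  report
}

.writeReport <- function(report, outputDir) {
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(as.data.frame(df),
                       file.path(outputDir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (st in names(report$de)) wt(report$de[[st]], paste0("de_", st))
  wt(report$deCounts, "de_counts")
  for (st in names(report$enrichment))
    wt(report$enrichment[[st]], paste0("enrichment_", st))
  for (st in names(report$shift)) wt(report$shift[[st]],
                                     paste0("shift_", st))
  for (st in names(report$modules)) {
    lab <- moduleLabels(report$modules[[st]])
    wt(data.frame(gene = names(lab), module = lab), paste0("modules_", st))
    eg <- eigengenes(report$modules[[st]])
    if (nrow(eg))
      utils::write.table(eg, file.path(outputDir,
                                       paste0("eigengenes_", st, ".tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
  }
  utils::write.table(report$stateFractions,
                     file.path(outputDir, "state_fractions.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(report$deconvolution)) wt(report$deconvolution,
                                         "deconvolution")
  if (!is.null(report$prioritized)) {
    it <- report$prioritized$test
    jsonlite::write_json(
      list(N = it@backgroundSize, sizes = it@setSizes,
           observed = it@observed, expected = it@expected,
           p_upper = it@pUpper, genes = report$prioritized$genes),
      file.path(outputDir, "intersection.json"), auto_unbox = TRUE,
      digits = NA)
  }
  invisible(outputDir)
}
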