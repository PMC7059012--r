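#' @importFrom withr with_seed
NULL

# Derive a reproducible sub-seed from a master seed and a step name, so that
# every generator sub-step consumes an independent, named stream. Kept below
# .Machine$integer.max.
.subSeed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647L)
}

.withSeed <- function(seed, code) withr::with_seed(seed, code)

# log(sum(exp(x))) without overflow; -Inf-safe
.logSumExp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Read gene sets from a GMT file
#'
#' GMT is one set per line: name, description, then tab-separated members.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set names).
#' @export
writeGmt <- function(sets, path, descriptions = names(sets)) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked gene list in RNK format (gene, metric)
#'
#' @param ranked data.frame/DataFrame with columns `gene` and `metric`.
#' @param path file path.
#' @export
writeRnk <- function(ranked, path) {
  utils::write.table(data.frame(gene = ranked$gene, metric = ranked$metric),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an RNK file into a ranked table
#'
#' @param path file path.
#' @return DataFrame with `gene` and `metric`, sorted most-up to most-down.
#' @export
readRnk <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("gene", "metric"),
                         colClasses = c("character", "numeric"))
  d <- d[order(d$metric, decreasing = TRUE), ]
  DataFrame(gene = d$gene, metric = d$metric)
}

#' Write a BulkExperiment as TSV (counts + sample metadata)
#'
#' The count matrix is written as a gene-by-sample TSV with a header row of
#' sample ids and gene ids in the first column; the sample table as a TSV
#' with columns sample_id, strain, age, genotype and any further covariates.
#'
#' @param be a [BulkExperiment-class].
#' @param countsPath,samplesPath output file paths.
#' @export
writeBulkTsv <- function(be, countsPath, samplesPath) {
  cts <- assay(be, "counts")
  df <- data.frame(gene = rownames(cts), cts, check.names = FALSE)
  utils::write.table(df, countsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sam <- as.data.frame(colData(be))
  sam <- cbind(sample_id = colnames(be), sam)
  utils::write.table(sam, samplesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(countsPath, samplesPath))
}

#' Read a BulkExperiment from TSV files written by [writeBulkTsv()]
#'
#' @param countsPath,samplesPath input file paths.
#' @return a [BulkExperiment-class].
#' @export
readBulkTsv <- function(countsPath, samplesPath) {
  cts <- utils::read.table(countsPath, sep = "\t", header = TRUE,
                           check.names = FALSE)
  rownames(cts) <- cts$gene
  cts$gene <- NULL
  sam <- utils::read.table(samplesPath, sep = "\t", header = TRUE,
                           colClasses = "character")
  rownames(sam) <- sam$sample_id
  sam$sample_id <- NULL
  if ("concentration" %in% colnames(sam))
    sam$concentration <- as.numeric(sam$concentration)
  BulkExperiment(as.matrix(cts), sam[colnames(cts), , drop = FALSE])
}

#' Write single-cell counts in 10x-style MTX format
#'
#' Emits `matrix.mtx` (1-based Matrix Market coordinates), `features.tsv`
#' and `barcodes.tsv` into `dir`.
#'
#' @param ce a [CellExperiment-class].
#' @param dir output directory (created if absent).
#' @export
write10x <- function(ce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- as(assay(ce, "counts"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  utils::write.table(as.data.frame(colData(ce)),
                     file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(dir)
}

#' Read single-cell counts written by [write10x()]
#'
#' @param dir directory with matrix.mtx, features.tsv, barcodes.tsv and the
#'   per-cell metadata table cells.tsv.
#' @param mitoGenes optional explicit mitochondrial gene ids; defaults to
#'   features starting with `"mt-"`.
#' @return a [CellExperiment-class].
#' @export
read10x <- function(dir, mitoGenes = NULL) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- as(m, "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  cells <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                             header = TRUE, row.names = 1)
  if (is.null(mitoGenes))
    mitoGenes <- grep("^mt-", rownames(m), value = TRUE)
  ts <- if ("trueState" %in% colnames(cells))
    cells[colnames(m), "trueState"] else NULL
  CellExperiment(m, groups = cells[colnames(m), "group"],
                 mitoGenes = mitoGenes, trueState = ts)
}
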