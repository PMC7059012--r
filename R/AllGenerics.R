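#' @include AllClasses.R
NULL

#' Accessors for GroundTruth
#'
#' @param x a [GroundTruth-class] object.
#' @return the corresponding slot: character gene ids, named numeric
#'   effects/p-values, a group-by-state fraction matrix, or a named numeric
#'   microgliosis factor per group.
#' @name GroundTruth-accessors
#' @aliases deGenes interactionLfc riskGenes moduleAssignment stateFractions
#'   microgliosisFactor
NULL

#' @rdname GroundTruth-accessors
#' @export
setGeneric("deGenes", function(x) standardGeneric("deGenes"))
#' @rdname GroundTruth-accessors
#' @export
setMethod("deGenes", "GroundTruth", function(x) x@deGenes)

#' @rdname GroundTruth-accessors
#' @export
setGeneric("interactionLfc", function(x) standardGeneric("interactionLfc"))
#' @rdname GroundTruth-accessors
#' @export
setMethod("interactionLfc", "GroundTruth", function(x) x@interactionLfc)

#' @rdname GroundTruth-accessors
#' @export
setGeneric("riskGenes", function(x) standardGeneric("riskGenes"))
#' @rdname GroundTruth-accessors
#' @export
setMethod("riskGenes", "GroundTruth", function(x) x@riskGenes)

#' @rdname GroundTruth-accessors
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))
#' @rdname GroundTruth-accessors
#' @export
setMethod("moduleAssignment", "GroundTruth", function(x) x@moduleAssignment)

#' @rdname GroundTruth-accessors
#' @export
setGeneric("stateFractions", function(x) standardGeneric("stateFractions"))
#' @rdname GroundTruth-accessors
#' @export
setMethod("stateFractions", "GroundTruth", function(x) x@stateFractions)

#' @rdname GroundTruth-accessors
#' @export
setGeneric("microgliosisFactor",
           function(x) standardGeneric("microgliosisFactor"))
#' @rdname GroundTruth-accessors
#' @export
setMethod("microgliosisFactor", "GroundTruth",
          function(x) x@microgliosisFactor)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth (seed ", object@seed, ")\n", sep = "")
  cat("  interaction DE genes: ", length(object@deGenes), "\n", sep = "")
  cat("  risk genes:           ", length(object@riskGenes), "\n", sep = "")
  if (nrow(object@stateFractions))
    cat("  state fractions:      ", nrow(object@stateFractions), " groups x ",
        ncol(object@stateFractions), " states\n", sep = "")
  if (length(object@microgliosisFactor))
    cat("  microgliosis factor:  [",
        paste(format(range(object@microgliosisFactor), digits = 3),
              collapse = ", "), "]\n", sep = "")
})

#' Accessors for ModulePartition
#'
#' @param x a [ModulePartition-class] object.
#' @name ModulePartition-accessors
NULL

#' @rdname ModulePartition-accessors
#' @return `moduleLabels()`: named character vector, gene -> module.
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @rdname ModulePartition-accessors
#' @export
setMethod("moduleLabels", "ModulePartition", function(x) x@labels)

#' @rdname ModulePartition-accessors
#' @return `eigengenes()`: module-by-sample matrix of eigengene profiles.
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))
#' @rdname ModulePartition-accessors
#' @export
setMethod("eigengenes", "ModulePartition", function(x) x@eigengenes)

#' @rdname ModulePartition-accessors
#' @return `tomMatrix()`: the topological overlap matrix.
#' @export
setGeneric("tomMatrix", function(x) standardGeneric("tomMatrix"))
#' @rdname ModulePartition-accessors
#' @export
setMethod("tomMatrix", "ModulePartition", function(x) x@tom)

#' @rdname ModulePartition-accessors
#' @return `moduleSizes()`: named integer vector of module sizes, largest
#'   first, excluding `"unassigned"`.
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))
#' @rdname ModulePartition-accessors
#' @export
setMethod("moduleSizes", "ModulePartition", function(x) {
  tab <- table(x@labels[x@labels != "unassigned"])
  sort(tab, decreasing = TRUE)
})

#' @rdname ModulePartition-accessors
#' @param module module name.
#' @return `moduleGenes()`: gene ids belonging to `module`.
#' @export
setGeneric("moduleGenes", function(x, module) standardGeneric("moduleGenes"))
#' @rdname ModulePartition-accessors
#' @export
setMethod("moduleGenes", "ModulePartition", function(x, module) {
  names(x@labels)[x@labels == module]
})

setMethod("show", "ModulePartition", function(object) {
  sz <- moduleSizes(object)
  cat("ModulePartition: ", length(object@labels), " genes, ",
      length(sz), " modules\n", sep = "")
  if (length(sz)) {
    shown <- utils::head(sz, 8)
    cat("  sizes: ", paste(names(shown), shown, sep = "=", collapse = " "),
        if (length(sz) > 8) " ..." else "", "\n", sep = "")
  }
  cat("  unassigned: ", sum(object@labels == "unassigned"), "\n", sep = "")
})

#' Accessors for IntersectionTest
#'
#' @param x an [IntersectionTest-class] object.
#' @name IntersectionTest-accessors
NULL

#' @rdname IntersectionTest-accessors
#' @return `pUpper()`: upper-tail p-value P(X >= observed).
#' @export
setGeneric("pUpper", function(x) standardGeneric("pUpper"))
#' @rdname IntersectionTest-accessors
#' @export
setMethod("pUpper", "IntersectionTest", function(x) x@pUpper)

#' @rdname IntersectionTest-accessors
#' @return `expectedOverlap()`: expected intersection size in genes.
#' @export
setGeneric("expectedOverlap", function(x) standardGeneric("expectedOverlap"))
#' @rdname IntersectionTest-accessors
#' @export
setMethod("expectedOverlap", "IntersectionTest", function(x) x@expected)

#' @rdname IntersectionTest-accessors
#' @return `overlapDistribution()`: named numeric vector P(X = x).
#' @export
setGeneric("overlapDistribution",
           function(x) standardGeneric("overlapDistribution"))
#' @rdname IntersectionTest-accessors
#' @export
setMethod("overlapDistribution", "IntersectionTest",
          function(x) x@distribution)

setMethod("show", "IntersectionTest", function(object) {
  cat("IntersectionTest: k = ", length(object@setSizes),
      " sets over N = ", object@backgroundSize, "\n", sep = "")
  cat("  sizes:    ", paste(object@setSizes, collapse = ", "), "\n", sep = "")
  cat("  observed: ", object@observed,
      "  expected: ", format(object@expected, digits = 4), "\n", sep = "")
  cat("  P(X >= observed) = ", format(object@pUpper, digits = 4), "\n",
      sep = "")
})
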