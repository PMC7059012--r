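#' @include AllClasses.R utils.R
NULL

#' Exact distribution of a multi-set intersection size
#'
#' The null model draws k sets of fixed sizes independently and uniformly
#' from a background of N genes. The distribution of the size of their
#' common intersection is computed by iterated hypergeometric convolution:
#' if the running intersection of the first j sets has size m, it meets the
#' next set of size n in `Hypergeometric(N, m, n)` genes. Computation is in
#' log space so tail masses of order 1e-11 and below at N around 16,000
#' remain accurate.
#'
#' @param N background size.
#' @param setSizes integer sizes n_1..n_k (k >= 2, all <= N).
#' @return named numeric vector `P(X = x)` for `x = 0..min(setSizes)`.
#' @export
intersectionDistribution <- function(N, setSizes) {
  setSizes <- as.integer(setSizes)
  if (length(setSizes) < 2) stop("need at least 2 sets")
  if (any(setSizes > N)) stop("set sizes must not exceed the background N")
  if (any(setSizes < 0) || N < 1) stop("sizes must be non-negative, N >= 1")
  logd <- rep(-Inf, setSizes[1] + 1)
  logd[setSizes[1] + 1] <- 0          # first set intersects itself fully
  for (n in setSizes[-1]) {
    mMax <- length(logd) - 1L
    newMax <- min(mMax, n)
    newLog <- vapply(0:newMax, function(j) {
      terms <- logd + stats::dhyper(j, 0:mMax, N - (0:mMax), n, log = TRUE)
      .logSumExp(terms[is.finite(terms)])
    }, numeric(1))
    logd <- newLog
  }
  d <- exp(logd)
  names(d) <- 0:(length(d) - 1L)
  d / sum(d)
}

#' Expected multi-set intersection size
#'
#' `N * prod(n_i / N)` - the expectation of the exact distribution under
#' independent uniform draws.
#'
#' @inheritParams intersectionDistribution
#' @return expected overlap in genes.
#' @export
expectedIntersection <- function(N, setSizes) {
  if (any(setSizes > N)) stop("set sizes must not exceed the background N")
  N * prod(setSizes / N)
}

#' Exact multi-set intersection test
#'
#' Upper-tail probability `P(X >= observed)` of the exact intersection-size
#' distribution - the prioritization statistic for asking whether k gene
#' sets share more genes than chance allows. One-sided (enrichment
#' direction) only; adjust across families of tests with [adjustBY()].
#'
#' @inheritParams intersectionDistribution
#' @param observed observed intersection size; must lie within the feasible
#'   support `[max(0, sum(n_i) - (k-1) N), min(n_i)]`.
#' @return an [IntersectionTest-class].
#' @export
intersectionTest <- function(N, setSizes, observed) {
  d <- intersectionDistribution(N, setSizes)
  lo <- max(0, sum(setSizes) - (length(setSizes) - 1) * N)
  hi <- min(setSizes)
  if (observed < lo || observed > hi)
    stop("observed overlap ", observed, " outside feasible support [",
         lo, ", ", hi, "]")
  x <- as.integer(names(d))
  pU <- sum(d[x >= observed])
  new("IntersectionTest", backgroundSize = as.integer(N),
      setSizes = as.integer(setSizes), observed = as.integer(observed),
      expected = expectedIntersection(N, setSizes), pUpper = pU,
      distribution = d)
}

#' Intersection test for named gene sets over a background list
#'
#' Convenience wrapper: intersects the supplied sets with the background,
#' counts the common overlap, and runs [intersectionTest()].
#'
#' @param sets named list of character vectors (e.g. read with
#'   [readGmt()]).
#' @param background character background gene list.
#' @return an [IntersectionTest-class]; the common genes are attached as
#'   `attr(, "genes")`.
#' @export
intersectionTestSets <- function(sets, background) {
  if (!length(background)) stop("empty background")
  sets <- lapply(sets, intersect, background)
  common <- Reduce(intersect, sets)
  it <- intersectionTest(length(unique(background)),
                         vapply(sets, length, integer(1)), length(common))
  attr(it, "genes") <- common
  it
}
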