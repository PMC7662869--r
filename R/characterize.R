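#' Distinctiveness between two coefficient vectors
#'
#' `1 - Spearman rank correlation`, in `[0, 2]`: 0 for identical rankings,
#' 1 for unrelated models, 2 for exactly reversed rankings. Symmetric and
#' invariant under strictly monotone transforms of either vector.
#'
#' @param coefA,coefB equal-length numeric coefficient vectors (non-constant).
#' @return Single distinctiveness value.
#' @export
distinctiveness <- function(coefA, coefB) {
  if (length(coefA) != length(coefB))
    stop("coefficient vectors must have equal length")
  if (stats::sd(coefA) == 0 || stats::sd(coefB) == 0)
    stop("Spearman correlation undefined for a constant coefficient vector")
  1 - stats::cor(coefA, coefB, method = "spearman")
}

#' Bootstrap confidence interval for distinctiveness
#'
#' Percentile interval obtained by resampling edges with replacement and
#' recomputing `1 - Spearman correlation` per resample. Edge resampling is an
#' interpretation: subject-level resampling is not available at the
#' coefficient level, so the interval reflects uncertainty over the edge set
#' rather than over subjects.
#'
#' @param coefA,coefB equal-length coefficient vectors.
#' @param nBoot bootstrap resamples.
#' @param seed RNG seed.
#' @param level confidence level.
#' @return List with `estimate`, `ciLow`, `ciHigh`, `nBoot`.
#' @export
distinctivenessCI <- function(coefA, coefB, nBoot = 1000L, seed = 1L,
                              level = 0.95) {
  est <- distinctiveness(coefA, coefB)
  n <- length(coefA)
  set.seed(seed)
  vals <- vapply(seq_len(nBoot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    1 - stats::cor(coefA[idx], coefB[idx], method = "spearman")
  }, numeric(1))
  a <- (1 - level) / 2
  ci <- stats::quantile(vals, c(a, 1 - a), names = FALSE)
  list(estimate = est, ciLow = ci[1], ciHigh = ci[2],
       nBoot = as.integer(nBoot))
}

#' Mean per-fold coefficient vector of a cross-validated model
#'
#' The coefficient summary used for cross-condition comparison: the
#' entrywise mean of the per-fold coefficient vectors (expanded to the full
#' feature space when folds used feature selection).
#'
#' @param cv a [CvPrediction-class].
#' @return Numeric coefficient vector.
#' @export
meanCoefficients <- function(cv) {
  Reduce(`+`, foldCoefficients(cv, full = TRUE)) / length(cv@models)
}

#' Reliability of coefficients across folds
#'
#' All pairwise Pearson correlations between per-fold coefficient vectors,
#' summarized as mean and standard deviation (sd 0 for a single pair).
#' Constant vectors are excluded with a warning.
#'
#' @param coefList list of equal-length coefficient vectors (>= 2), or a
#'   [CvPrediction-class].
#' @return Named numeric vector `c(mean, sd)`.
#' @export
foldReliability <- function(coefList) {
  if (is(coefList, "CvPrediction")) coefList <- foldCoefficients(coefList)
  keep <- vapply(coefList, function(v) stats::sd(v) > 0, logical(1))
  if (any(!keep)) {
    warning(sprintf("excluding %d constant coefficient vectors", sum(!keep)))
    coefList <- coefList[keep]
  }
  if (length(coefList) < 2L) stop("need at least 2 non-constant fold vectors")
  M <- do.call(cbind, coefList)
  C <- stats::cor(M)
  vals <- C[upper.tri(C)]
  c(mean = mean(vals), sd = if (length(vals) > 1L) stats::sd(vals) else 0)
}

#' Summarize a model's most informative edges by functional network
#'
#' Selects the top fraction of edges by absolute coefficient
#' (`round-half-away-from-zero(fraction * nEdges)` edges; 0.1% of 35,778
#' edges is 36), maps each to its node pair and network pair via the atlas,
#' and aggregates counts and summed absolute coefficients per unordered
#' network pair. Ties break by ascending edge index; the result is invariant
#' to a global sign flip of the coefficients.
#'
#' @param coefficients edge coefficient vector of length `n(n-1)/2` for the
#'   atlas's `n` nodes.
#' @param atlas a [NetworkAtlas-class].
#' @param fraction selection fraction in (0, 1] (default 0.001).
#' @return An [EdgeNetworkSummary-class].
#' @export
topEdgeSummary <- function(coefficients, atlas, fraction = 0.001) {
  stopifnot(is(atlas, "NetworkAtlas"))
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  n <- nNodes(atlas)
  nE <- n * (n - 1L) / 2L
  if (length(coefficients) != nE)
    stop(sprintf("expected %d coefficients for a %d-node atlas", nE, n))
  m <- max(1L, as.integer(floor(fraction * nE + 0.5)))
  sel <- order(-abs(coefficients), seq_along(coefficients))[seq_len(m)]
  pairs <- edgePairs(n)[sel, , drop = FALSE]
  net <- networkLabels(atlas)
  edges <- data.frame(
    edge = sel,
    nodeI = pairs[, "i"],
    nodeJ = pairs[, "j"],
    coefficient = coefficients[sel],
    networkI = net[pairs[, "i"]],
    networkJ = net[pairs[, "j"]],
    stringsAsFactors = FALSE
  )
  a <- pmin(edges$networkI, edges$networkJ)
  b <- pmax(edges$networkI, edges$networkJ)
  key <- paste(a, b, sep = " | ")
  agg <- data.frame(
    networkA = tapply(a, key, `[`, 1),
    networkB = tapply(b, key, `[`, 1),
    count = as.integer(tapply(key, key, length)),
    totalAbsCoefficient = as.numeric(tapply(abs(edges$coefficient), key, sum)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  agg <- agg[order(-agg$count, agg$networkA, agg$networkB), ]
  rownames(agg) <- NULL
  new("EdgeNetworkSummary", edges = edges, pairSummary = agg,
      fraction = fraction)
}

#' Correlation between component scores and a covariate
#'
#' Product-moment correlation with the two-sided t-based p-value; used to
#' check, e.g., that mean frame-to-frame displacement is not associated with
#' the behavioral components, and for score-vs-external-scale checks.
#'
#' @param scores,covariate equal-length non-constant numeric vectors.
#' @return List with `r`, `p`, `n`.
#' @export
scoreCovariateCorrelation <- function(scores, covariate) {
  if (length(scores) != length(covariate))
    stop("scores and covariate must have equal length")
  if (stats::sd(scores) == 0 || stats::sd(covariate) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(scores, covariate)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(scores))
}
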