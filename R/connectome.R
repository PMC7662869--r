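#' Canonical edge ordering of an n-node parcellation
#'
#' Edges are the upper-triangle node pairs `(i, j)`, `i < j`, enumerated
#' row-major: `(1,2), (1,3), ..., (1,n), (2,3), ...`. A 268-node atlas yields
#' `268 * 267 / 2 = 35,778` edges.
#'
#' @param nNodes node count.
#' @return Integer matrix with columns `i`, `j`, one row per edge in
#'   canonical order.
#' @export
edgePairs <- function(nNodes) {
  M <- matrix(0L, nNodes, nNodes)
  lt <- lower.tri(M)
  cbind(i = col(M)[lt], j = row(M)[lt])
}

#' Vectorize a connectivity matrix to its canonical edge vector
#'
#' @param m a [ConnectivityMatrix-class] or symmetric numeric matrix.
#' @return Numeric vector of length `n(n-1)/2` in canonical row-major
#'   upper-triangle order, with attribute `nNodes`.
#' @seealso [devectorizeEdges()], [edgePairs()]
#' @export
vectorizeEdges <- function(m) {
  v <- if (is(m, "ConnectivityMatrix")) connMatrix(m) else as.matrix(m)
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-10)
    stop("input must be a symmetric square matrix")
  # column-major lower triangle of a symmetric matrix == row-major upper triangle
  out <- v[lower.tri(v)]
  attr(out, "nNodes") <- nrow(v)
  out
}

#' Rebuild a connectivity matrix from a canonical edge vector
#'
#' @param edges numeric vector of length `nNodes * (nNodes - 1) / 2`.
#' @param nNodes node count.
#' @return A [ConnectivityMatrix-class]; `devectorizeEdges(vectorizeEdges(M))`
#'   reproduces `M` exactly off the diagonal.
#' @export
devectorizeEdges <- function(edges, nNodes = attr(edges, "nNodes")) {
  if (is.null(nNodes)) stop("nNodes must be supplied")
  nE <- nNodes * (nNodes - 1L) / 2L
  if (length(edges) != nE)
    stop(sprintf("edge vector has length %d; expected %d for %d nodes",
                 length(edges), nE, nNodes))
  M <- matrix(0, nNodes, nNodes)
  M[lower.tri(M)] <- as.numeric(edges)
  M <- M + t(M)
  ConnectivityMatrix(M)
}

#' Stack connectomes into a subjects x edges feature matrix
#'
#' @param connectomes list of [ConnectivityMatrix-class] (or symmetric
#'   matrices) with equal node counts, or an already-stacked edge matrix.
#' @return subjects x edges numeric matrix with attribute `nNodes`.
#' @export
edgeMatrix <- function(connectomes) {
  if (is.matrix(connectomes) && !is.null(attr(connectomes, "nNodes")))
    return(connectomes)
  rows <- lapply(connectomes, vectorizeEdges)
  n <- unique(vapply(rows, length, integer(1)))
  if (length(n) != 1L) stop("connectomes differ in node count")
  out <- do.call(rbind, rows)
  attr(out, "nNodes") <- attr(rows[[1]], "nNodes")
  out
}

#' Build the nuisance regressor matrix for one run
#'
#' Columns: intercept; orthogonal polynomial drifts of order 1..`driftOrder`
#' (linear, quadratic, cubic by default; zero-mean); a 24-parameter motion
#' expansion of the 6 base realignment parameters (the 6 parameters, their
#' one-frame backward differences with the first frame set to 0, and the
#' squares of both); and any supplied tissue/global-signal columns.
#'
#' @param run a [TimeSeriesRun-class], or a frame x 6 base motion matrix.
#' @param tissue optional frame x k tissue/global columns (taken from the run
#'   when a run is supplied).
#' @param driftOrder polynomial drift order (default 3).
#' @return frame x regressor numeric matrix.
#' @export
buildConfoundMatrix <- function(run, tissue = NULL, driftOrder = 3L) {
  if (is(run, "TimeSeriesRun")) {
    mp <- run@motionParams
    if (is.null(tissue)) tissue <- run@tissue
  } else {
    mp <- as.matrix(run)
  }
  if (ncol(mp) != 6L)
    stop("base motion parameters must have 6 columns (3 translation, 3 rotation)")
  nf <- nrow(mp)
  d <- rbind(0, diff(mp))
  motion24 <- cbind(mp, d, mp^2, d^2)
  colnames(motion24) <- c(sprintf("mot%d", 1:6), sprintf("mot%d_d", 1:6),
                          sprintf("mot%d_sq", 1:6), sprintf("mot%d_dsq", 1:6))
  drift <- stats::poly(seq_len(nf), driftOrder)
  colnames(drift) <- sprintf("drift%d", seq_len(driftOrder))
  out <- cbind(intercept = 1, drift, motion24)
  if (!is.null(tissue) && ncol(as.matrix(tissue)) > 0L) {
    tissue <- as.matrix(tissue)
    if (nrow(tissue) != nf) stop("tissue columns must have one row per frame")
    if (is.null(colnames(tissue)))
      colnames(tissue) <- sprintf("tissue%d", seq_len(ncol(tissue)))
    out <- cbind(out, tissue)
  }
  out
}

#' Regress nuisance covariates out of node time series
#'
#' Ordinary least squares per node; residuals are orthogonal to every
#' retained confound column. Collinear confound columns are dropped with a
#' warning (rank determined by pivoted QR).
#'
#' @param series node x frame matrix.
#' @param confounds frame x regressor matrix.
#' @return Residual node x frame matrix.
#' @export
regressConfounds <- function(series, confounds) {
  series <- as.matrix(series)
  confounds <- as.matrix(confounds)
  if (ncol(series) != nrow(confounds))
    stop("series frames and confound rows must match")
  qrC <- qr(confounds)
  if (qrC$rank < ncol(confounds)) {
    drop <- colnames(confounds)[qrC$pivot[(qrC$rank + 1L):ncol(confounds)]]
    warning("dropping collinear confound columns: ",
            paste(drop, collapse = ", "))
    confounds <- confounds[, qrC$pivot[seq_len(qrC$rank)], drop = FALSE]
    qrC <- qr(confounds)
  }
  t(qr.resid(qrC, t(series)))
}

#' Temporally smooth node time series with a Gaussian filter
#'
#' Per-node convolution along time with a normalized Gaussian kernel
#' (half-width `ceiling(4 sigma)`), reflective boundary handling. The default
#' `sigma = 1.95` frames corresponds to an approximate 0.12 Hz cutoff at the
#' acquisition's 0.8 s repetition time.
#'
#' @param series node x frame matrix (>= 5 frames).
#' @param sigma Gaussian width in frames (> 0).
#' @return Smoothed node x frame matrix.
#' @export
temporalSmooth <- function(series, sigma = 1.95) {
  if (sigma <= 0) stop("sigma must be positive")
  series <- as.matrix(series)
  nf <- ncol(series)
  if (nf < 5L) stop("need at least 5 frames")
  h <- ceiling(4 * sigma)
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  # reflective padding: frame h..1 mirrored in front, nf..nf-h+1 at the back
  padIdx <- c(pmin(h:1, nf), seq_len(nf), pmax(nf - seq_len(h) + 1L, 1L))
  P <- series[, padIdx, drop = FALSE]
  out <- t(apply(P, 1L, function(x)
    stats::filter(x, k, method = "convolution", sides = 2L)[(h + 1L):(h + nf)]))
  dimnames(out) <- dimnames(series)
  out
}

#' Compute a Fisher-z functional connectivity matrix
#'
#' Pearson correlations between every pair of node time courses, clipped to
#' `±(1 - 1e-7)` and Fisher z-transformed (`atanh`); diagonal set to 0.
#'
#' @param series node x frame matrix; every node must be non-constant.
#' @return A [ConnectivityMatrix-class].
#' @export
computeConnectivity <- function(series) {
  series <- as.matrix(series)
  sds <- apply(series, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(series)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant node time series: ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(series))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  ConnectivityMatrix(z)
}

#' Motion quality control for one run
#'
#' A run fails if its mean frame-to-frame displacement, maximum displacement,
#' or maximum rotation strictly exceeds the respective threshold ("more
#' than"); values exactly at a threshold pass. Worsening any field can never
#' turn a failing run into a passing one.
#'
#' @param motion one-row data.frame (or list) with `meanFfd`,
#'   `maxDisplacement`, `maxRotation` (see [generateMotion()]).
#' @param thresholds a [QcThresholds-class].
#' @return List with `pass` (logical) and `reasons` (character, one entry per
#'   violated criterion; empty when passing).
#' @export
qcMotion <- function(motion, thresholds = QcThresholds()) {
  reasons <- character()
  if (motion$meanFfd > thresholds@maxMeanFfd)
    reasons <- c(reasons, sprintf("mean FFD %.3g mm > %.3g mm",
                                  motion$meanFfd, thresholds@maxMeanFfd))
  if (motion$maxDisplacement > thresholds@maxDisplacement)
    reasons <- c(reasons, sprintf("max displacement %.3g mm > %.3g mm",
                                  motion$maxDisplacement, thresholds@maxDisplacement))
  if (motion$maxRotation > thresholds@maxRotation)
    reasons <- c(reasons, sprintf("max rotation %.3g deg > %.3g deg",
                                  motion$maxRotation, thresholds@maxRotation))
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Motion QC report over many runs
#'
#' @param motion data.frame of motion summaries (one row per run; see
#'   [generateMotion()]).
#' @param thresholds a [QcThresholds-class].
#' @return data.frame with `subject` (if present), `pass`, `reasons`
#'   (collapsed with "; ").
#' @export
qcReport <- function(motion, thresholds = QcThresholds()) {
  res <- lapply(seq_len(nrow(motion)), function(i)
    qcMotion(motion[i, , drop = FALSE], thresholds))
  data.frame(
    subject = if ("subject" %in% names(motion)) motion$subject
              else as.character(seq_len(nrow(motion))),
    pass = vapply(res, `[[`, logical(1), "pass"),
    reasons = vapply(res, function(r) paste(r$reasons, collapse = "; "),
                     character(1)),
    stringsAsFactors = FALSE
  )
}

#' Average connectivity across QC-passing runs
#'
#' Entrywise mean of Fisher-z matrices (variance-stabilized scale), used to
#' combine up to four rest runs or the two runs of a task.
#'
#' @param matrices non-empty list of [ConnectivityMatrix-class] with equal
#'   node counts.
#' @return A [ConnectivityMatrix-class].
#' @export
aggregateRuns <- function(matrices) {
  if (length(matrices) == 0L)
    stop("no QC-passing runs: subject must be excluded upstream")
  vals <- lapply(matrices, function(m)
    if (is(m, "ConnectivityMatrix")) connMatrix(m) else as.matrix(m))
  n <- unique(vapply(vals, nrow, integer(1)))
  if (length(n) != 1L) stop("runs differ in node count")
  ConnectivityMatrix(Reduce(`+`, vals) / length(vals))
}

#' Process one run into a connectivity matrix
#'
#' The fixed preprocessing order: build the nuisance design, regress it from
#' the node series, temporally smooth the residuals, then correlate and
#' Fisher-z. Swapping regression and smoothing changes the result; the order
#' here is pinned by a regression test.
#'
#' @param run a [TimeSeriesRun-class].
#' @param sigma smoothing width in frames.
#' @param driftOrder polynomial drift order.
#' @return A [ConnectivityMatrix-class].
#' @export
processRun <- function(run, sigma = 1.95, driftOrder = 3L) {
  stopifnot(is(run, "TimeSeriesRun"))
  C <- buildConfoundMatrix(run, driftOrder = driftOrder)
  res <- regressConfounds(run@series, C)
  computeConnectivity(temporalSmooth(res, sigma))
}
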