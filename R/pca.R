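## Internal: loadings + explained variance by SVD with deterministic signs.
## Each loading column is flipped so its largest-|value| element is positive
## (first such element on ties), making fits reproducible across platforms.
.pcaCore <- function(X, nComponents = NULL) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  sv <- svd(Xc)
  d <- sv$d
  tot <- sum(d^2)
  if (tot <= 0) stop("input has no variance")
  rank <- sum(d > d[1] * 1e-9)
  maxK <- min(rank, ncol(X))
  if (rank < min(nrow(X) - 1L, ncol(X)))
    warning(sprintf("rank-deficient input: components truncated at rank %d", rank))
  K <- if (is.null(nComponents)) maxK else min(nComponents, maxK)
  L <- sv$v[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    i <- which.max(abs(L[, k]))
    if (L[i, k] < 0) L[, k] <- -L[, k]
  }
  rownames(L) <- colnames(X)
  colnames(L) <- sprintf("PC%d", seq_len(K))
  list(loadings = L, evf = d[seq_len(K)]^2 / tot, center = ctr,
       d = d, rank = rank)
}

.emptyTransform <- function() {
  new("TransformParams", lambda = numeric(0), center = numeric(0),
      scale = numeric(0))
}

#' Fit a principal-component model by singular value decomposition
#'
#' Columns are centered (the caller normally supplies an already standardized
#' matrix, see [applyTransform()]); loadings are right singular vectors under
#' a deterministic sign convention, and explained-variance fractions are
#' squared singular values over total variance. Rank-deficient input warns
#' and truncates at the numerical rank.
#'
#' @param X subjects x items numeric matrix.
#' @param nComponents components to retain; default all (up to rank).
#' @return A [ComponentModel-class].
#' @seealso [selectDimensionality()], [projectScores()]
#' @export
fitPca <- function(X, nComponents = NULL) {
  core <- .pcaCore(X, nComponents)
  new("ComponentModel",
      loadings = core$loadings,
      explainedVariance = core$evf,
      nComponents = ncol(core$loadings),
      center = core$center,
      scale = rep(1, length(core$center)),
      transform = .emptyTransform())
}

## Laplace approximation to the log-evidence of probabilistic PCA at rank k
## (Minka's criterion; the Bayesian model selection the behavioral analysis
## uses to retain components). spectrum = eigenvalues of the sample
## covariance, descending; n = sample size.
.laplaceEvidence <- function(spectrum, k, n) {
  p <- length(spectrum)
  eps <- 1e-15
  if (spectrum[k] < eps) return(-Inf)
  i <- seq_len(k)
  pu <- -k * log(2) +
    sum(lgamma((p - i + 1) / 2) - (p - i + 1) / 2 * log(pi))
  pl <- -n / 2 * sum(log(spectrum[i]))
  v <- max(eps, sum(spectrum[-i]) / (p - k))
  pv <- -n * (p - k) / 2 * log(v)
  m <- p * k - k * (k + 1) / 2
  pp <- (m + k) / 2 * log(2 * pi)
  shat <- spectrum
  shat[(k + 1):p] <- v
  pa <- 0
  for (a in seq_len(k)) {
    j <- (a + 1):p
    pa <- pa + sum(log((spectrum[a] - spectrum[j]) *
                       (1 / shat[j] - 1 / shat[a])) + log(n))
  }
  pu + pl + pv + pp - pa / 2 - k / 2 * log(n)
}

#' Select PCA dimensionality by Bayesian model selection
#'
#' Evaluates the Laplace-approximation log-evidence of probabilistic PCA at
#' every rank `1..min(n-1, p-1)` and returns the maximizing rank (smallest on
#' ties). This is the criterion that retains 14 components on the full
#' behavioral battery; on synthetic low-rank-plus-noise data it recovers the
#' planted rank.
#'
#' @param X subjects x items numeric matrix (standardized items).
#' @param maxRank optional cap on the ranks examined.
#' @return Integer selected rank.
#' @export
selectDimensionality <- function(X, maxRank = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (p < 3L) stop("need at least 3 items to select dimensionality")
  Xc <- sweep(X, 2L, colMeans(X), "-")
  spectrum <- svd(Xc, nu = 0, nv = 0)$d^2 / (n - 1)
  spectrum <- sort(spectrum, decreasing = TRUE)
  if (length(spectrum) < p) spectrum <- c(spectrum, rep(0, p - length(spectrum)))
  ranks <- seq_len(min(n - 1L, p - 1L, if (is.null(maxRank)) p else maxRank))
  ev <- vapply(ranks, function(k) .laplaceEvidence(spectrum, k, n), numeric(1))
  ranks[which.max(ev)]
}

## Greedy alignment of fitted components to a reference: assign by maximal
## |correlation| of loading columns (ties by component index), then flip each
## matched column so the correlation is positive.
.alignComponents <- function(reference, fitted) {
  C <- suppressWarnings(stats::cor(reference, fitted))
  C[!is.finite(C)] <- 0
  K <- ncol(reference)
  ord <- integer(K)
  sgn <- numeric(K)
  A <- abs(C)
  for (step in seq_len(K)) {
    idx <- which.max(A)  # column-major: ties -> smallest ref, then fitted index
    r <- (idx - 1L) %% K + 1L
    cc <- (idx - 1L) %/% K + 1L
    ord[r] <- cc
    sgn[r] <- if (C[r, cc] >= 0) 1 else -1
    A[r, ] <- -Inf
    A[, cc] <- -Inf
  }
  list(order = ord, signs = sgn)
}

#' Align one loading matrix (or model) to a reference
#'
#' Greedy assignment by maximal absolute correlation between loading columns,
#' followed by a sign flip to positive correlation. Used to make bootstrap
#' replicates and split-half fits comparable despite PCA's sign and order
#' indeterminacy.
#'
#' @param reference,fitted item x component loading matrices (or
#'   [ComponentModel-class] objects) over the same items.
#' @return `fitted`'s loadings reordered and sign-flipped to match
#'   `reference`, with attributes `order` and `signs`.
#' @export
alignLoadings <- function(reference, fitted) {
  R <- if (is(reference, "ComponentModel")) componentLoadings(reference) else as.matrix(reference)
  Fm <- if (is(fitted, "ComponentModel")) componentLoadings(fitted) else as.matrix(fitted)
  if (nrow(R) != nrow(Fm)) stop("loading matrices must cover the same items")
  K <- min(ncol(R), ncol(Fm))
  al <- .alignComponents(R[, seq_len(K), drop = FALSE], Fm[, seq_len(K), drop = FALSE])
  out <- sweep(Fm[, al$order, drop = FALSE], 2L, al$signs, "*")
  dimnames(out) <- list(rownames(R), colnames(R)[seq_len(K)])
  attr(out, "order") <- al$order
  attr(out, "signs") <- al$signs
  out
}

#' Bootstrap confidence intervals for component loadings
#'
#' Resamples subjects with replacement, restandardizes and refits the PCA on
#' each resample, aligns the replicate components to the reference model
#' (assignment by maximal |correlation|, sign-flipped positive), and returns
#' percentile 2.5/97.5 bounds per loading. A loading is reliable when its
#' interval excludes zero. Resamples in which an item collapses to zero
#' variance are redrawn (with a message).
#'
#' @param X the subjects x items matrix the reference was fitted on.
#' @param reference a [ComponentModel-class] fitted on `X`.
#' @param nBoot bootstrap replicates (>= 100; the full analysis uses 10,000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return A [BootstrapLoadingSummary-class].
#' @export
bootstrapLoadings <- function(X, reference, nBoot = 1000L, seed = 1L,
                              level = 0.95) {
  stopifnot(nBoot >= 100L)
  X <- as.matrix(X)
  n <- nrow(X)
  ref <- componentLoadings(reference)
  K <- ncol(ref)
  set.seed(seed)
  draws <- array(NA_real_, c(nrow(ref), K, nBoot))
  redraws <- 0L
  for (b in seq_len(nBoot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      s <- apply(Xb, 2L, stats::sd)
      if (all(s > 0)) break
      redraws <- redraws + 1L
      if (redraws > 10L * nBoot) stop("too many degenerate resamples")
    }
    Xb <- scale(Xb)
    core <- .pcaCore(Xb, K)
    Lb <- core$loadings
    if (ncol(Lb) < K) next  # rank-collapsed resample: leave NA, dropped below
    al <- .alignComponents(ref, Lb)
    draws[, , b] <- sweep(Lb[, al$order, drop = FALSE], 2L, al$signs, "*")
  }
  if (redraws > 0L)
    message(sprintf("redrew %d degenerate bootstrap resamples", redraws))
  a <- (1 - level) / 2
  lower <- apply(draws, c(1, 2), stats::quantile, probs = a, na.rm = TRUE)
  upper <- apply(draws, c(1, 2), stats::quantile, probs = 1 - a, na.rm = TRUE)
  dimnames(lower) <- dimnames(upper) <- dimnames(ref)
  new("BootstrapLoadingSummary", lower = lower, upper = upper,
      reliable = lower > 0 | upper < 0, nBoot = as.integer(nBoot))
}

#' Project subjects onto a fitted component space
#'
#' When the model carries fitted normalization parameters and raw responses
#' are supplied, the Yeo-Johnson transform and standardization are applied
#' first; the (centered, scaled) matrix is then multiplied by the loadings.
#' Projecting the training matrix reproduces the fitted scores.
#'
#' @param newdata an [ItemResponseTable-class] (raw responses) or a numeric
#'   matrix already on the scale the model was fitted on.
#' @param model a [ComponentModel-class].
#' @return subjects x components score matrix.
#' @export
projectScores <- function(newdata, model) {
  hasTransform <- length(model@transform@lambda) > 0L
  if (is(newdata, "ItemResponseTable")) {
    if (!hasTransform)
      stop("model has no transform parameters; supply a standardized matrix")
    Z <- applyTransform(newdata, model@transform)
  } else {
    Z <- as.matrix(newdata)
    items <- rownames(model@loadings)
    if (!is.null(colnames(Z)) && !is.null(items)) {
      if (!all(items %in% colnames(Z)))
        stop("newdata is missing items: ",
             paste(setdiff(items, colnames(Z)), collapse = ", "))
      Z <- Z[, items, drop = FALSE]
    } else if (ncol(Z) != nrow(model@loadings)) {
      stop("newdata items do not match the model")
    }
  }
  Z <- sweep(sweep(Z, 2L, model@center, "-"), 2L, model@scale, "/")
  S <- Z %*% model@loadings
  rownames(S) <- rownames(Z)
  S
}

#' Similarity between two component models
#'
#' Pearson correlation of matched loading columns after aligning the second
#' model to the first (order and sign). Used to verify that loadings refitted
#' on an independent behavioral subset reproduce the reference structure
#' (r > 0.9 in the full analysis).
#'
#' @param modelA,modelB [ComponentModel-class] objects (or loading matrices)
#'   over the same items.
#' @return Named numeric vector of per-component correlations.
#' @export
loadingSimilarity <- function(modelA, modelB) {
  A <- if (is(modelA, "ComponentModel")) componentLoadings(modelA) else as.matrix(modelA)
  if (is(modelB, "ComponentModel") || is.matrix(modelB) || is.data.frame(modelB)) {
    B <- alignLoadings(A, modelB)
  } else stop("modelB must be a ComponentModel or loading matrix")
  K <- ncol(B)
  r <- vapply(seq_len(K), function(k) stats::cor(A[, k], B[, k]), numeric(1))
  names(r) <- colnames(A)[seq_len(K)]
  r
}

#' Multidimensional scaling of item distances
#'
#' Classical (Torgerson) MDS of pairwise Euclidean distances between item
#' columns, alongside the item Pearson correlation matrix — the descriptive
#' view that separates the risk-seeking block from the familial block.
#'
#' @param X subjects x items matrix (>= 3 items), typically the
#'   transformed/standardized responses.
#' @param k embedding dimension (default 2).
#' @return List with `coordinates` (items x k, deterministic axis signs),
#'   `correlations` (item correlation matrix) and `distances` (the input
#'   distance matrix as a `dist`).
#' @export
itemMds <- function(X, k = 2L) {
  X <- as.matrix(X)
  if (ncol(X) < 3L) stop("need at least 3 items")
  D <- stats::dist(t(X))
  coords <- stats::cmdscale(D, k = k)
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- colnames(X)
  list(coordinates = coords, correlations = stats::cor(X), distances = D)
}

#' Fit the full behavioral dimensionality-reduction pipeline
#'
#' Convenience wrapper for the stage-one analysis: fit per-item Yeo-Johnson
#' normalization, standardize, fit the PCA, and (optionally) choose the
#' component count by Bayesian model selection.
#'
#' @param responses an [ItemResponseTable-class].
#' @param nComponents retained components; `NULL` selects the rank by
#'   [selectDimensionality()].
#' @return A [ComponentModel-class] carrying the transform, ready for
#'   [projectScores()].
#' @export
fitComponentModel <- function(responses, nComponents = NULL) {
  params <- fitTransform(responses)
  Z <- applyTransform(responses, params)
  if (is.null(nComponents)) nComponents <- selectDimensionality(Z)
  model <- fitPca(Z, nComponents = nComponents)
  model@transform <- params
  model
}
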