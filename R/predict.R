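#' Default ridge penalty grid
#'
#' Thirteen log-spaced values from 1e-3 to 1e5, spanning near-OLS to heavy
#' shrinkage.
#'
#' @return Numeric vector, ascending.
#' @export
defaultAlphaGrid <- function() 10^seq(-3, 5, length.out = 13L)

#' Random k-fold assignment
#'
#' Uniform random permutation split into k near-equal blocks (fold sizes
#' differ by at most one); deterministic under `seed`.
#'
#' @param nSubjects subject count (>= k).
#' @param k fold count (default 10).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`, one per subject.
#' @export
makeFolds <- function(nSubjects, k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  if (nSubjects < k) stop("need at least k subjects")
  set.seed(seed)
  perm <- sample.int(nSubjects)
  sizes <- rep(nSubjects %/% k, k) + c(rep(1L, nSubjects %% k),
                                       rep(0L, k - nSubjects %% k))
  out <- integer(nSubjects)
  out[perm] <- rep(seq_len(k), sizes)
  out
}

#' Leakage-safe feature standardization
#'
#' Columns are z-scored using training-set means and standard deviations
#' only; the identical transformation is applied to the test rows.
#' Zero-variance training columns are set to zero in both sets.
#'
#' @param train training subjects x features matrix (>= 2 rows).
#' @param test optional test matrix with the same columns.
#' @return List with `train`, `test` (or `NULL`), `center`, `scale` (the raw
#'   training sds; zero where the column was constant).
#' @export
standardizeTrainApply <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2L) stop("need at least 2 training subjects")
  mu <- colMeans(train)
  sigma <- sqrt(colSums(sweep(train, 2L, mu, "-")^2) / (nrow(train) - 1L))
  div <- ifelse(sigma > 0, sigma, 1)
  ztr <- sweep(sweep(train, 2L, mu, "-"), 2L, div, "/")
  ztr[, sigma == 0] <- 0
  zte <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test)
    zte <- sweep(sweep(test, 2L, mu, "-"), 2L, div, "/")
    zte[, sigma == 0] <- 0
  }
  list(train = ztr, test = zte, center = mu, scale = sigma)
}

## Eigen-based dual ridge solve: given eig = eigen(K) of the training Gram,
## return the dual weights for centered outcome c at penalty alpha.
## Eigenvalues below a relative floor are treated as zero (minimum-norm
## solution when alpha = 0).
.dualWeights <- function(eig, cvec, alpha) {
  d <- eig$values
  uc <- crossprod(eig$vectors, cvec)
  da <- d + alpha
  inv <- ifelse(da > max(d, 0) * 1e-12, 1 / da, 0)
  as.numeric(eig$vectors %*% (uc * inv))
}

#' Fit ridge regression
#'
#' Solves `(X'X + alpha I) beta = X'(y - ybar)` with an unpenalized intercept
#' equal to the training mean of `y`. For `p > n` the exact dual (kernel)
#' identity `beta = X'(XX' + alpha I)^{-1}(y - ybar)` is used. `X` is
#' expected to be standardized already (see [standardizeTrainApply()]).
#'
#' @param X subjects x features matrix.
#' @param y outcome vector.
#' @param alpha L2 penalty (>= 0).
#' @return A [RidgeModel-class].
#' @export
ridgeFit <- function(X, y, alpha) {
  X <- as.matrix(X)
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("alpha must be a single value >= 0")
  if (nrow(X) != length(y)) stop("X rows and y length must match")
  ybar <- mean(y)
  cvec <- y - ybar
  n <- nrow(X); p <- ncol(X)
  if (p <= n) {
    A <- crossprod(X)
    diag(A) <- diag(A) + alpha
    beta <- tryCatch(as.numeric(solve(A, crossprod(X, cvec))),
                     error = function(e) {
                       eig <- eigen(crossprod(X), symmetric = TRUE)
                       uc <- crossprod(eig$vectors, crossprod(X, cvec))
                       da <- eig$values + alpha
                       inv <- ifelse(da > max(eig$values, 0) * 1e-12, 1 / da, 0)
                       as.numeric(eig$vectors %*% (uc * inv))
                     })
  } else {
    eig <- eigen(tcrossprod(X), symmetric = TRUE)
    beta <- as.numeric(crossprod(X, .dualWeights(eig, cvec, alpha)))
  }
  new("RidgeModel", coefficients = beta, intercept = ybar, alpha = alpha,
      featureCenter = numeric(0), featureScale = numeric(0),
      selected = integer(0))
}

#' Predict from a ridge model
#'
#' Applies the stored feature selection and training-set standardization (if
#' present), then the linear model.
#'
#' @param object a [RidgeModel-class].
#' @param newdata subjects x features matrix on the scale the model was
#'   given; when the model stores standardization parameters, `newdata` is
#'   raw and standardized here.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
setMethod("predict", "RidgeModel", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (length(object@selected) && ncol(X) != length(object@coefficients))
    X <- X[, object@selected, drop = FALSE]
  if (length(object@featureCenter)) {
    div <- ifelse(object@featureScale > 0, object@featureScale, 1)
    X <- sweep(sweep(X, 2L, object@featureCenter, "-"), 2L, div, "/")
    X[, object@featureScale == 0] <- 0
  }
  as.numeric(X %*% object@coefficients + object@intercept)
})

## Tune alpha on a precomputed Gram matrix.
## K: n x n Gram of the (already standardized) training features;
## innerFolds: fold id per training subject; eigens: optional cached
## per-inner-fold eigendecompositions and cross-Gram projections.
.gramTune <- function(K, y, innerFolds, alphaGrid, eigens = NULL) {
  ks <- sort(unique(innerFolds))
  R <- matrix(NA_real_, length(ks), length(alphaGrid))
  for (gi in seq_along(ks)) {
    ite <- which(innerFolds == ks[gi])
    itr <- which(innerFolds != ks[gi])
    if (is.null(eigens)) {
      eig <- eigen(K[itr, itr], symmetric = TRUE)
      KteU <- K[ite, itr, drop = FALSE] %*% eig$vectors
    } else {
      eig <- eigens[[gi]]$eig
      KteU <- eigens[[gi]]$KteU
    }
    ybar <- mean(y[itr])
    uc <- crossprod(eig$vectors, y[itr] - ybar)
    dmax <- max(eig$values, 0)
    for (ai in seq_along(alphaGrid)) {
      da <- eig$values + alphaGrid[ai]
      inv <- ifelse(da > dmax * 1e-12, 1 / da, 0)
      pred <- KteU %*% (uc * inv) + ybar
      r <- suppressWarnings(stats::cor(as.numeric(pred), y[ite]))
      R[gi, ai] <- r
    }
  }
  meanR <- colMeans(R, na.rm = TRUE)
  if (all(!is.finite(meanR))) {
    warning("all inner-fold correlations undefined; falling back to the grid median")
    return(list(alpha = stats::median(alphaGrid), meanR = meanR))
  }
  meanR[!is.finite(meanR)] <- -Inf
  list(alpha = alphaGrid[which.max(meanR)], meanR = meanR)
}

#' Tune the ridge penalty by inner cross-validation
#'
#' Splits the training sample into `innerK` folds and returns the grid value
#' maximizing the mean inner-held-out Pearson correlation between predictions
#' and observations (ties go to the smaller alpha; the grid is sorted
#' ascending). `X` is used as given — inside the outer CV it has already been
#' standardized with the outer training fold's parameters, and the inner loop
#' runs entirely within that training sample.
#'
#' @param X training subjects x features matrix.
#' @param y training outcomes.
#' @param alphaGrid candidate penalties.
#' @param innerK inner fold count (default 10).
#' @param seed RNG seed for the inner fold assignment.
#' @return Selected alpha (a single grid value).
#' @export
tuneAlpha <- function(X, y, alphaGrid = defaultAlphaGrid(), innerK = 10L,
                      seed = 1L) {
  if (length(alphaGrid) == 0L) stop("alphaGrid must be non-empty")
  alphaGrid <- sort(as.numeric(alphaGrid))
  if (length(alphaGrid) == 1L) return(alphaGrid)
  X <- as.matrix(X)
  innerFolds <- makeFolds(nrow(X), innerK, seed)
  .gramTune(tcrossprod(X), y, innerFolds, alphaGrid)$alpha
}

#' Select edges by univariate train-set correlation
#'
#' Indices of the `kEdges` features with the largest absolute Pearson
#' correlation with the outcome, computed on training subjects only; ties
#' break by ascending index, and constant features count as correlation 0.
#'
#' @param X training subjects x features matrix.
#' @param y training outcomes.
#' @param kEdges number of features to keep (1..ncol(X)).
#' @return Integer feature indices (ascending correlation rank order).
#' @export
univariateSelect <- function(X, y, kEdges) {
  X <- as.matrix(X)
  if (kEdges <= 0L) stop("kEdges must be positive")
  if (kEdges > ncol(X)) stop("kEdges exceeds the number of features")
  r <- suppressWarnings(as.numeric(stats::cor(X, y)))
  r[!is.finite(r)] <- 0
  order(-abs(r), seq_along(r))[seq_len(kEdges)]
}

## Derive the per-fold seed for inner fold assignment; kept small and
## deterministic so cached and uncached code paths agree exactly.
.foldSeed <- function(seed, fold) (as.integer(seed) %% 100000L) * 101L + fold

#' Cross-validated connectome-based prediction
#'
#' For each outer fold: optionally select the top-`selectK` edges by
#' univariate train-set correlation, z-score edges with training-set
#' parameters, tune alpha by inner 10-fold cross-validation within the
#' training sample, fit the ridge model, and predict the held-out subjects.
#' Every subject is predicted exactly once; per-fold models (coefficients,
#' tuned alpha, standardization, selected edges) are retained.
#'
#' @param X subjects x edges feature matrix.
#' @param y per-subject component scores.
#' @param folds fold assignment from [makeFolds()]; built from `k` and `seed`
#'   when `NULL`.
#' @param k outer fold count when `folds` is `NULL`.
#' @param alphaGrid ridge penalty grid.
#' @param seed RNG seed (outer folds when needed, and inner fold splits).
#' @param selectK optional univariate feature-selection count per fold.
#' @param innerK inner fold count.
#' @param condition condition label stored with the result.
#' @return A [CvPrediction-class].
#' @export
crossValidatedPredict <- function(X, y, folds = NULL, k = 10L,
                                  alphaGrid = defaultAlphaGrid(), seed = 1L,
                                  selectK = NULL, innerK = 10L,
                                  condition = "condition") {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows and y length must match")
  if (is.null(folds)) folds <- makeFolds(nrow(X), k, seed)
  folds <- as.integer(folds)
  alphaGrid <- sort(as.numeric(alphaGrid))
  nFold <- max(folds)
  pred <- rep(NA_real_, length(y))
  models <- vector("list", nFold)
  for (f in seq_len(nFold)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (length(tr) < 2L) stop("every fold needs at least 2 training subjects")
    sel <- if (is.null(selectK)) integer(0)
           else univariateSelect(X[tr, , drop = FALSE], y[tr], selectK)
    Xf <- if (length(sel)) X[, sel, drop = FALSE] else X
    std <- standardizeTrainApply(Xf[tr, , drop = FALSE], Xf[te, , drop = FALSE])
    K <- tcrossprod(std$train)
    innerFolds <- makeFolds(length(tr), innerK, .foldSeed(seed, f))
    alpha <- if (length(alphaGrid) == 1L) alphaGrid
             else .gramTune(K, y[tr], innerFolds, alphaGrid)$alpha
    eig <- eigen(K, symmetric = TRUE)
    ybar <- mean(y[tr])
    w <- .dualWeights(eig, y[tr] - ybar, alpha)
    beta <- as.numeric(crossprod(std$train, w))
    pred[te] <- as.numeric(std$test %*% beta + ybar)
    models[[f]] <- new("RidgeModel", coefficients = beta, intercept = ybar,
                       alpha = alpha, featureCenter = std$center,
                       featureScale = std$scale, selected = sel)
  }
  new("CvPrediction", predicted = pred, observed = as.numeric(y),
      folds = folds, models = models, nFeatures = ncol(X),
      condition = condition)
}

#' Per-fold coefficient vectors of a cross-validated model
#'
#' @param cv a [CvPrediction-class].
#' @param full expand coefficients of feature-selected folds back to the full
#'   feature space (zeros elsewhere) so folds are comparable.
#' @return List of numeric coefficient vectors, one per fold.
#' @export
foldCoefficients <- function(cv, full = TRUE) {
  lapply(cv@models, function(m) {
    if (full && length(m@selected)) {
      out <- numeric(cv@nFeatures)
      out[m@selected] <- m@coefficients
      out
    } else m@coefficients
  })
}

#' Concatenate edge matrices across scan conditions
#'
#' Stacks per-condition subjects x edges matrices column-wise for subjects
#' meeting inclusion criteria in every condition. Columns are grouped by
#' condition (in the supplied order) with edges in canonical order within
#' each block; the provenance map records the (condition, edge) behind every
#' column. Four 268-node conditions give `4 * 35,778 = 143,112` columns.
#'
#' @param edgeMatrices named list of subjects x edges matrices with identical
#'   subject row names and ordering.
#' @param labels condition labels (defaults to the list names).
#' @return List with `X` (combined matrix) and `provenance` (data.frame:
#'   column, condition, edge).
#' @export
concatenateConditions <- function(edgeMatrices, labels = names(edgeMatrices)) {
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- sprintf("condition%d", seq_along(edgeMatrices))
  ref <- rownames(edgeMatrices[[1]])
  for (i in seq_along(edgeMatrices)[-1]) {
    ids <- rownames(edgeMatrices[[i]])
    if (!identical(ids, ref)) {
      off <- union(setdiff(ids, ref), setdiff(ref, ids))
      if (length(off) == 0L) off <- "(same set, different order)"
      stop("subject sets/order differ across conditions: ",
           paste(utils::head(off, 10), collapse = ", "))
    }
  }
  X <- do.call(cbind, edgeMatrices)
  prov <- data.frame(
    column = seq_len(ncol(X)),
    condition = rep(labels, vapply(edgeMatrices, ncol, integer(1))),
    edge = unlist(lapply(edgeMatrices, function(m) seq_len(ncol(m)))),
    stringsAsFactors = FALSE
  )
  list(X = X, provenance = prov)
}

#' Partial correlation adjusted for covariates
#'
#' Pearson correlation of the residuals after least-squares regression of
#' both vectors on an intercept plus the covariate columns — the performance
#' statistic `r_p`, adjusting predicted-observed agreement for head motion
#' and data quantity. With no covariates this is the plain Pearson
#' correlation.
#'
#' @param pred,obs numeric vectors of equal length.
#' @param Z optional covariate matrix/data.frame (subjects x covariates);
#'   collinear columns are dropped with a warning.
#' @return Partial correlation `r_p`.
#' @export
partialCorr <- function(pred, obs, Z = NULL) {
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  if (is.null(Z) || NCOL(Z) == 0L || (is.matrix(Z) && ncol(Z) == 0L))
    return(stats::cor(pred, obs))
  Z <- as.matrix(Z)
  if (length(pred) < ncol(Z) + 3L)
    stop("need at least (number of covariates + 3) subjects")
  D <- cbind(1, Z)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    keep <- qrD$pivot[seq_len(qrD$rank)]
    warning("dropping collinear covariate columns")
    D <- D[, keep, drop = FALSE]
    qrD <- qr(D)
  }
  stats::cor(qr.resid(qrD, pred), qr.resid(qrD, obs))
}

#' Bootstrap confidence interval for covariate-adjusted performance
#'
#' Resamples subjects with replacement, recomputes the partial correlation
#' per resample, and returns percentile 2.5/97.5 bounds (the full analysis
#' uses 10,000 resamples). Resamples with degenerate residuals are skipped
#' and counted; more than 50% degenerate resamples is an error.
#'
#' @param pred,obs per-subject predicted and observed scores.
#' @param Z optional covariate matrix (see [partialCorr()]).
#' @param nBoot bootstrap resamples (default 10,000).
#' @param seed RNG seed.
#' @param level confidence level.
#' @return A [PerformanceEstimate-class].
#' @export
bootstrapPerformance <- function(pred, obs, Z = NULL, nBoot = 10000L,
                                 seed = 1L, level = 0.95) {
  rp <- partialCorr(pred, obs, Z)
  n <- length(pred)
  Zm <- if (is.null(Z)) NULL else as.matrix(Z)
  set.seed(seed)
  vals <- rep(NA_real_, nBoot)
  for (b in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    vals[b] <- tryCatch(
      suppressWarnings(partialCorr(pred[idx], obs[idx],
                                   if (is.null(Zm)) NULL
                                   else Zm[idx, , drop = FALSE])),
      error = function(e) NA_real_)
  }
  bad <- sum(!is.finite(vals))
  if (bad > nBoot / 2)
    stop(sprintf("%d of %d bootstrap resamples degenerate", bad, nBoot))
  if (bad > 0L)
    message(sprintf("skipped %d degenerate bootstrap resamples", bad))
  ok <- vals[is.finite(vals)]
  a <- (1 - level) / 2
  if (length(ok) == 1L) {
    ci <- c(ok, ok)
  } else {
    ci <- stats::quantile(ok, c(a, 1 - a), names = FALSE)
  }
  new("PerformanceEstimate", rp = rp, ciLow = ci[1], ciHigh = ci[2],
      nBoot = as.integer(nBoot),
      covariates = if (is.null(Zm)) character(0)
                   else (colnames(Zm) %||% sprintf("z%d", seq_len(ncol(Zm)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation null distribution of cross-validated performance
#'
#' Reruns the full leakage-safe pipeline — per-fold standardization, inner
#' alpha tuning, ridge fit, out-of-fold prediction — for each permutation of
#' the outcome, and also for the observed outcome. The feature-side
#' computations (standardization parameters, Gram matrices and their
#' inner-fold eigendecompositions) depend only on `X` and the fold split, so
#' they are computed once and shared across permutations; alpha tuning and
#' model fitting rerun per permutation. Folds are held fixed across
#' permutations (exchangeable under the null).
#'
#' @param X subjects x edges matrix.
#' @param y outcomes.
#' @param nPerm number of permutations.
#' @param folds optional fold assignment; built from `k`, `seed` otherwise.
#' @param k outer fold count.
#' @param alphaGrid ridge penalty grid.
#' @param seed RNG seed (folds, inner splits, permutations).
#' @param innerK inner fold count.
#' @param Z optional covariates for the performance statistic.
#' @return List with `observed` (r_p on the true outcome) and `null` (numeric
#'   vector of permuted-outcome r_p values).
#' @export
permutationNull <- function(X, y, nPerm = 100L, folds = NULL, k = 10L,
                            alphaGrid = defaultAlphaGrid(), seed = 1L,
                            innerK = 10L, Z = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(folds)) folds <- makeFolds(n, k, seed)
  folds <- as.integer(folds)
  alphaGrid <- sort(as.numeric(alphaGrid))
  nFold <- max(folds)
  ## Build the y-independent cache
  cache <- vector("list", nFold)
  for (f in seq_len(nFold)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    std <- standardizeTrainApply(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    K <- tcrossprod(std$train)
    Kte <- std$test %*% t(std$train)
    innerFolds <- makeFolds(length(tr), innerK, .foldSeed(seed, f))
    ks <- sort(unique(innerFolds))
    inner <- vector("list", length(ks))
    for (gi in seq_along(ks)) {
      itr <- which(innerFolds != ks[gi])
      ite <- which(innerFolds == ks[gi])
      eig <- eigen(K[itr, itr], symmetric = TRUE)
      inner[[gi]] <- list(eig = eig,
                          KteU = K[ite, itr, drop = FALSE] %*% eig$vectors)
    }
    eigK <- eigen(K, symmetric = TRUE)
    cache[[f]] <- list(tr = tr, te = te, innerFolds = innerFolds,
                       inner = inner, eigK = eigK,
                       KteU = Kte %*% eigK$vectors)
    rm(std, K, Kte)
  }
  runOne <- function(yy) {
    pred <- rep(NA_real_, n)
    for (f in seq_len(nFold)) {
      cf <- cache[[f]]
      ytr <- yy[cf$tr]
      alpha <- if (length(alphaGrid) == 1L) alphaGrid
               else .gramTune(NULL, ytr, cf$innerFolds, alphaGrid,
                              eigens = cf$inner)$alpha
      ybar <- mean(ytr)
      uc <- crossprod(cf$eigK$vectors, ytr - ybar)
      da <- cf$eigK$values + alpha
      inv <- ifelse(da > max(cf$eigK$values, 0) * 1e-12, 1 / da, 0)
      pred[cf$te] <- as.numeric(cf$KteU %*% (uc * inv)) + ybar
    }
    partialCorr(pred, yy, Z)
  }
  observed <- runOne(y)
  set.seed(seed + 7919L)
  nullVals <- vapply(seq_len(nPerm), function(p) runOne(y[sample.int(n)]),
                     numeric(1))
  list(observed = observed, null = nullVals)
}

#' Assemble the standard motion covariate matrix
#'
#' The single-condition covariate set: mean frame-to-frame displacement,
#' mean rotation, maximum displacement, and number of frames. For the
#' combined model, pass per-condition motion tables: mean FFD, maximum
#' displacement and maximum rotation are averaged across conditions and
#' frames are totalled.
#'
#' @param motion a motion data.frame (see [generateMotion()]) or, for the
#'   combined model, a list of such data.frames (one per condition, same
#'   subject order).
#' @param columns covariate columns for the single-condition case.
#' @return Numeric subjects x covariates matrix with column names.
#' @export
motionCovariates <- function(motion,
                             columns = c("meanFfd", "meanRotation",
                                         "maxDisplacement", "nFrames")) {
  if (is.data.frame(motion)) {
    miss <- setdiff(columns, names(motion))
    if (length(miss)) stop("motion table lacks columns: ",
                           paste(miss, collapse = ", "))
    return(as.matrix(motion[, columns, drop = FALSE]))
  }
  stopifnot(is.list(motion), length(motion) >= 1L)
  avg <- function(col) rowMeans(vapply(motion, function(m) m[[col]],
                                       numeric(nrow(motion[[1]]))))
  cbind(meanFfd = avg("meanFfd"),
        maxDisplacement = avg("maxDisplacement"),
        maxRotation = avg("maxRotation"),
        nFrames = rowSums(vapply(motion, function(m) as.numeric(m$nFrames),
                                 numeric(nrow(motion[[1]])))))
}
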