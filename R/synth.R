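#' Generate synthetic item responses with planted latent factors
#'
#' Emulates a substance-use battery: latent factor scores are drawn from
#' `N(0, factorCov)`, each item's continuous latent is the loading-weighted
#' factor combination plus Gaussian noise with variance
#' `max(1 - Var(loading-weighted part), 0.05)` (so at unit total variance the
#' item-factor correlation equals the loading), and a monotone zero-inflated
#' transform imposes the right skew: with severity `s > 0` the response is
#' `round(expm1(latent - s))` where `latent > s` and 0 otherwise — fewer
#' subjects endorse an item as severity increases. With `s = 0` the item stays
#' continuous and linear in the latent (shifted by its minimum so responses
#' are non-negative; correlations are unaffected).
#'
#' @param nSubjects number of subjects (>= 2).
#' @param spec a [FactorSpec-class].
#' @param seed RNG seed; identical seeds give bit-identical tables.
#' @return List with `responses` (an [ItemResponseTable-class]) and `factors`
#'   (subjects x factors matrix of true scores).
#' @examples
#' spec <- twoBlockFactorSpec()
#' sim <- generateItemResponses(100, spec, seed = 1)
#' dim(responseValues(sim$responses))
#' @export
generateItemResponses <- function(nSubjects, spec, seed = 1L) {
  stopifnot(is(spec, "FactorSpec"))
  validObject(spec)
  if (nSubjects < 2L) stop("nSubjects must be >= 2")
  L <- spec@itemLoadings
  K <- ncol(L)
  set.seed(seed)
  Fm <- matrix(stats::rnorm(nSubjects * K), nSubjects, K) %*% chol(spec@factorCov)
  colnames(Fm) <- sprintf("factor%d", seq_len(K))
  signalVar <- diag(L %*% spec@factorCov %*% t(L))
  noiseVar <- pmax(1 - signalVar, 0.05)
  latent <- Fm %*% t(L) +
    matrix(stats::rnorm(nSubjects * nrow(L)), nSubjects, nrow(L)) %*%
      diag(sqrt(noiseVar), nrow(L))
  vals <- latent
  for (j in seq_len(nrow(L))) {
    s <- spec@skewSeverity[j]
    if (s == 0) {
      vals[, j] <- latent[, j] - min(latent[, j])
    } else {
      z <- latent[, j] - s
      vals[, j] <- ifelse(z > 0, round(expm1(z)), 0)
    }
  }
  colnames(vals) <- rownames(L)
  rownames(vals) <- rownames(Fm) <- sprintf("sub%05d", seq_len(nSubjects))
  list(responses = ItemResponseTable(vals), factors = Fm)
}

#' Default two-block factor specification
#'
#' Ten items in two orthogonal blocks mirroring the structure of the
#' behavioral battery: a risk-seeking block (six items; curiosity, intention,
#' early sips) and a familial block (four items; family history, household
#' smoking), with moderate-to-strong loadings and right-skew severity 1.
#'
#' @param skewSeverity per-item skew severity (default 1).
#' @return A [FactorSpec-class].
#' @export
twoBlockFactorSpec <- function(skewSeverity = 1) {
  L <- rbind(
    riskCuriosity1 = c(0.80, 0),
    riskCuriosity2 = c(0.75, 0),
    riskIntention1 = c(0.70, 0),
    riskIntention2 = c(0.65, 0),
    riskEarlySip1  = c(0.60, 0),
    riskEarlySip2  = c(0.55, 0),
    famHistory1    = c(0, 0.80),
    famHistory2    = c(0, 0.70),
    famHousehold1  = c(0, 0.65),
    famHousehold2  = c(0, 0.60)
  )
  colnames(L) <- c("riskSeeking", "familial")
  FactorSpec(L, skewSeverity = skewSeverity)
}

#' Generate connectomes with a planted edge-score signal
#'
#' For each signal edge, the edge value is
#' `noiseSd * (r * z + sqrt(1 - r^2) * eps)` with `z` the standardized score
#' and `eps` standard normal, so the population edge-score correlation is
#' exactly `r`; non-signal edges are pure noise. Matrices are symmetric with
#' a zero diagonal.
#'
#' @param scores finite per-subject scores the signal edges track.
#' @param spec a [ConnectomeSignalSpec-class].
#' @param seed RNG seed.
#' @param format `"matrices"` (list of [ConnectivityMatrix-class]) or
#'   `"edges"` (subjects x edges matrix in canonical order, memory-friendly
#'   at 268 nodes).
#' @return Per `format`; the edge matrix carries attribute `nNodes`.
#' @export
generateConnectomes <- function(scores, spec, seed = 1L,
                                format = c("matrices", "edges")) {
  format <- match.arg(format)
  stopifnot(is(spec, "ConnectomeSignalSpec"))
  validObject(spec)
  if (length(scores) == 0L) stop("scores must be non-empty")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n <- length(scores)
  z <- as.numeric(scale(scores))
  if (any(!is.finite(z))) stop("scores must be non-constant")
  nE <- spec@nNodes * (spec@nNodes - 1L) / 2L
  set.seed(seed)
  E <- matrix(stats::rnorm(n * nE), n, nE)
  if (length(spec@signalEdges)) {
    r <- spec@effectSize
    E[, spec@signalEdges] <- outer(z, r) +
      sweep(E[, spec@signalEdges, drop = FALSE], 2L, sqrt(1 - r^2), "*")
  }
  E <- E * spec@noiseSd
  attr(E, "nNodes") <- spec@nNodes
  if (format == "edges") return(E)
  lapply(seq_len(n), function(i) devectorizeEdges(E[i, ], spec@nNodes))
}

#' Generate node time series with a target correlation structure
#'
#' Draws frames from a factorized (Cholesky) target covariance and adds
#' separable confound signals — polynomial drift, slow motion-like random
#' walks, and smooth tissue-like signals — returned as a regressor matrix so
#' downstream confound regression can be exercised against known ground
#' truth.
#'
#' @param nNodes,nFrames dimensions of the run.
#' @param targetCorr symmetric positive-definite correlation matrix (unit
#'   diagonal) of the underlying signal.
#' @param confoundAmplitudes amplitudes for the 12 confound regressors
#'   (3 drift, 6 motion, 3 tissue); recycled from length 1 or 3 (per family).
#'   Zero (default) yields pure signal.
#' @param seed RNG seed.
#' @return List with `series` (nodes x frames), `confounds` (frames x 12) and
#'   `motionParams` (frames x 6, the motion traces usable as base motion
#'   regressors).
#' @export
generateTimeseries <- function(nNodes, nFrames, targetCorr = diag(nNodes),
                               confoundAmplitudes = 0, seed = 1L) {
  targetCorr <- as.matrix(targetCorr)
  if (nrow(targetCorr) != nNodes || ncol(targetCorr) != nNodes)
    stop("targetCorr must be nNodes x nNodes")
  if (max(abs(targetCorr - t(targetCorr))) > 1e-8)
    stop("targetCorr must be symmetric")
  if (max(abs(diag(targetCorr) - 1)) > 1e-8)
    stop("targetCorr must have a unit diagonal")
  R <- tryCatch(chol(targetCorr), error = function(e)
    stop("targetCorr is not positive definite; cannot factorize", call. = FALSE))
  amps <- if (length(confoundAmplitudes) == 3L)
    rep(confoundAmplitudes, c(3L, 6L, 3L))
  else rep_len(confoundAmplitudes, 12L)
  set.seed(seed)
  S <- t(R) %*% matrix(stats::rnorm(nNodes * nFrames), nNodes, nFrames)
  tgrid <- seq_len(nFrames)
  drift <- stats::poly(tgrid, 3L)
  motion <- apply(matrix(stats::rnorm(nFrames * 6L, sd = 0.02), nFrames, 6L),
                  2L, cumsum)
  tissue <- apply(matrix(stats::rnorm(nFrames * 3L), nFrames, 3L), 2L,
                  function(x) as.numeric(stats::filter(x, 0.95, "recursive")))
  C <- cbind(drift, motion, tissue)
  colnames(C) <- c(sprintf("drift%d", 1:3), sprintf("motion%d", 1:6),
                   c("csf", "wm", "global"))
  Cs <- scale(C)
  mix <- matrix(stats::rnorm(12L * nNodes), 12L, nNodes)
  S <- S + t(Cs %*% (mix * amps))
  rownames(S) <- sprintf("node%03d", seq_len(nNodes))
  list(series = S, confounds = C, motionParams = motion)
}

#' Generate per-subject motion summaries
#'
#' Log-normal motion summaries (mean frame-to-frame displacement, maximum
#' displacement, maximum and mean rotation) plus a frame count. When
#' `confoundWith` is supplied, the latent normal behind mean FFD is
#' correlated with the scores at
#' `rho = strength * sqrt(exp(sdlog^2) - 1) / sdlog`, which makes the
#' *observed* lognormal mean FFD correlate with the scores at exactly
#' `strength` in population (Stein's lemma). The default `strength = 0`
#' mirrors the finding that motion was uncorrelated with the behavioral
#' components.
#'
#' @param nSubjects subject count (>= 1).
#' @param meanlogFfd,sdlogFfd lognormal parameters of mean FFD (mm); the
#'   defaults put the median at 0.08 mm, typical of a child cohort after QC.
#' @param confoundWith optional per-subject scores to correlate motion with.
#' @param strength target population correlation between mean FFD and
#'   `confoundWith`.
#' @param seed RNG seed.
#' @return data.frame with columns `subject`, `meanFfd`, `maxDisplacement`,
#'   `maxRotation`, `meanRotation`, `nFrames`; all motion values strictly
#'   positive.
#' @export
generateMotion <- function(nSubjects, meanlogFfd = log(0.08), sdlogFfd = 0.5,
                           confoundWith = NULL, strength = 0, seed = 1L) {
  if (nSubjects < 1L) stop("nSubjects must be >= 1")
  if (sdlogFfd <= 0) stop("sdlogFfd must be positive")
  set.seed(seed)
  if (!is.null(confoundWith)) {
    if (length(confoundWith) != nSubjects)
      stop("confoundWith must have one score per subject")
    rho <- strength * sqrt(expm1(sdlogFfd^2)) / sdlogFfd
    if (abs(rho) > 1)
      stop("strength too large for this sdlog; reduce strength or sdlog")
    z <- as.numeric(scale(confoundWith))
    w <- rho * z + sqrt(1 - rho^2) * stats::rnorm(nSubjects)
  } else {
    w <- stats::rnorm(nSubjects)
  }
  meanFfd <- exp(meanlogFfd + sdlogFfd * w)
  data.frame(
    subject = sprintf("sub%05d", seq_len(nSubjects)),
    meanFfd = meanFfd,
    maxDisplacement = exp(log(0.6) + 0.6 * stats::rnorm(nSubjects)),
    maxRotation = exp(log(0.7) + 0.6 * stats::rnorm(nSubjects)),
    meanRotation = exp(log(0.1) + 0.5 * stats::rnorm(nSubjects)),
    nFrames = pmax(1L, as.integer(round(
      exp(log(380) + 0.08 * stats::rnorm(nSubjects))))),
    stringsAsFactors = FALSE
  )
}
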