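#' @import methods
NULL

## ---------------------------------------------------------------------------
## Synthetic-data specifications
## ---------------------------------------------------------------------------

#' Latent-factor specification for synthetic item responses
#'
#' Describes the two-block latent structure the generator plants: each item
#' loads on one or more latent factors (e.g. a risk-seeking block and a
#' familial block), and a per-item skew severity controls how strongly the
#' continuous latent is pushed into a zero-inflated, right-skewed count.
#'
#' @slot itemLoadings numeric matrix, items x factors.
#' @slot skewSeverity non-negative numeric, one value per item (recycled from
#'   length 1). Zero keeps the item continuous (linear-Gaussian); larger values
#'   raise the zero-inflation threshold and sharpen the right tail.
#' @slot factorCov symmetric positive-semidefinite factor covariance.
#' @exportClass FactorSpec
setClass("FactorSpec",
  representation(
    itemLoadings = "matrix",
    skewSeverity = "numeric",
    factorCov    = "matrix"
  )
)

setValidity("FactorSpec", function(object) {
  L <- object@itemLoadings
  S <- object@factorCov
  msg <- character()
  if (!is.numeric(L) || any(!is.finite(L)))
    msg <- c(msg, "itemLoadings must be a finite numeric matrix")
  if (nrow(S) != ncol(S) || nrow(S) != ncol(L))
    msg <- c(msg, "factorCov must be square with one row per factor")
  else {
    if (max(abs(S - t(S))) > 1e-8)
      msg <- c(msg, "factorCov must be symmetric")
    else if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      msg <- c(msg, "factorCov must be positive semidefinite")
  }
  if (length(object@skewSeverity) != nrow(L))
    msg <- c(msg, "skewSeverity must have one value per item")
  if (any(object@skewSeverity < 0))
    msg <- c(msg, "skewSeverity must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a FactorSpec
#'
#' @param itemLoadings items x factors loading matrix.
#' @param skewSeverity per-item skew severity (>= 0); recycled from length 1.
#' @param factorCov factor covariance; defaults to the identity (orthogonal
#'   factors, mirroring the orthogonality of the first two behavioral
#'   components).
#' @return A [FactorSpec-class] object.
#' @export
FactorSpec <- function(itemLoadings,
                       skewSeverity = 0,
                       factorCov = diag(ncol(itemLoadings))) {
  itemLoadings <- as.matrix(itemLoadings)
  if (is.null(rownames(itemLoadings)))
    rownames(itemLoadings) <- sprintf("item%02d", seq_len(nrow(itemLoadings)))
  skewSeverity <- rep_len(as.numeric(skewSeverity), nrow(itemLoadings))
  new("FactorSpec", itemLoadings = itemLoadings,
      skewSeverity = skewSeverity, factorCov = as.matrix(factorCov))
}

#' Planted connectome signal specification
#'
#' Defines which edges of a synthetic connectome carry signal and at what
#' population edge-score correlation.
#'
#' @slot nNodes node count of the parcellation.
#' @slot signalEdges integer indices into the canonical upper-triangle edge
#'   vector (row-major, i < j).
#' @slot effectSize per-signal-edge population correlation with the score
#'   (|r| < 1), recycled from length 1.
#' @slot noiseSd positive scale of the edge noise.
#' @exportClass ConnectomeSignalSpec
setClass("ConnectomeSignalSpec",
  representation(
    nNodes      = "integer",
    signalEdges = "integer",
    effectSize  = "numeric",
    noiseSd     = "numeric"
  )
)

setValidity("ConnectomeSignalSpec", function(object) {
  nE <- object@nNodes * (object@nNodes - 1L) / 2L
  msg <- character()
  if (object@nNodes < 2L) msg <- c(msg, "nNodes must be >= 2")
  if (length(object@signalEdges) &&
      (min(object@signalEdges) < 1L || max(object@signalEdges) > nE))
    msg <- c(msg, sprintf("signalEdges must lie in 1..%d", nE))
  if (anyDuplicated(object@signalEdges))
    msg <- c(msg, "signalEdges must be unique")
  if (length(object@effectSize) != max(1L, length(object@signalEdges)))
    msg <- c(msg, "effectSize must match signalEdges (or have length 1)")
  if (any(abs(object@effectSize) >= 1))
    msg <- c(msg, "|effectSize| must be < 1")
  if (length(object@noiseSd) != 1L || object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' Construct a ConnectomeSignalSpec
#'
#' @param nNodes node count.
#' @param signalEdges edge indices (canonical upper-triangle order) carrying
#'   signal.
#' @param effectSize population edge-score correlation per signal edge
#'   (recycled from length 1).
#' @param noiseSd edge noise standard deviation.
#' @return A [ConnectomeSignalSpec-class] object.
#' @export
ConnectomeSignalSpec <- function(nNodes, signalEdges = integer(),
                                 effectSize = 0.3, noiseSd = 1) {
  signalEdges <- as.integer(signalEdges)
  new("ConnectomeSignalSpec",
      nNodes = as.integer(nNodes),
      signalEdges = signalEdges,
      effectSize = rep_len(as.numeric(effectSize), max(1L, length(signalEdges))),
      noiseSd = as.numeric(noiseSd))
}

## ---------------------------------------------------------------------------
## Behavioral containers
## ---------------------------------------------------------------------------

#' Subject-by-item behavioral response table
#'
#' Holds non-negative mixed-type questionnaire responses (binary, ordinal,
#' count) with optional item metadata such as reporter or substance class.
#'
#' @slot values numeric matrix, subjects x items; finite, non-negative.
#' @slot itemInfo data.frame of per-item metadata (one row per item).
#' @exportClass ItemResponseTable
setClass("ItemResponseTable",
  representation(values = "matrix", itemInfo = "data.frame")
)

setValidity("ItemResponseTable", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  else {
    if (any(!is.finite(v))) msg <- c(msg, "values must be finite (complete cases only)")
    else if (any(v < 0)) msg <- c(msg, "values must be non-negative")
  }
  if (is.null(colnames(v))) msg <- c(msg, "values must have item (column) names")
  if (nrow(object@itemInfo) && nrow(object@itemInfo) != ncol(v))
    msg <- c(msg, "itemInfo must have one row per item")
  if (length(msg)) msg else TRUE
})

#' Construct an ItemResponseTable
#'
#' @param values subjects x items numeric matrix (non-negative, finite).
#' @param itemInfo optional data.frame of per-item metadata.
#' @return An [ItemResponseTable-class] object.
#' @export
ItemResponseTable <- function(values, itemInfo = data.frame()) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("item%02d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("sub%05d", seq_len(nrow(values)))
  new("ItemResponseTable", values = values, itemInfo = itemInfo)
}

#' Per-item normalization parameters
#'
#' Yeo-Johnson lambda plus post-transform standardization constants for each
#' retained item.
#'
#' @slot lambda per-item power-transform parameter.
#' @slot center per-item mean of the transformed values.
#' @slot scale per-item standard deviation of the transformed values (> 0).
#' @exportClass TransformParams
setClass("TransformParams",
  representation(lambda = "numeric", center = "numeric", scale = "numeric")
)

setValidity("TransformParams", function(object) {
  n <- length(object@lambda)
  msg <- character()
  if (length(object@center) != n || length(object@scale) != n)
    msg <- c(msg, "lambda, center and scale must have equal length")
  if (any(object@scale <= 0)) msg <- c(msg, "scale must be positive")
  if (length(msg)) msg else TRUE
})

#' Principal-component model of behavioral items
#'
#' Loadings are the right singular vectors of the (column-centered)
#' standardized item matrix, with a deterministic sign convention; explained
#' variance fractions are squared singular values over total variance.
#'
#' @slot loadings item x component orthonormal matrix.
#' @slot explainedVariance per-component explained-variance fraction in
#'   \[0, 1\], non-increasing, summing to <= 1.
#' @slot nComponents retained component count.
#' @slot center,scale column centering/scaling applied to the PCA input.
#' @slot transform a [TransformParams-class] (may be empty when the model was
#'   fitted on a pre-standardized matrix).
#' @exportClass ComponentModel
setClass("ComponentModel",
  representation(
    loadings          = "matrix",
    explainedVariance = "numeric",
    nComponents       = "integer",
    center            = "numeric",
    scale             = "numeric",
    transform         = "TransformParams"
  )
)

setValidity("ComponentModel", function(object) {
  L <- object@loadings
  msg <- character()
  if (ncol(L) != object@nComponents)
    msg <- c(msg, "loadings must have nComponents columns")
  if (length(object@explainedVariance) != ncol(L))
    msg <- c(msg, "explainedVariance must have one entry per component")
  else {
    ev <- object@explainedVariance
    if (any(ev < -1e-12) || any(ev > 1 + 1e-12))
      msg <- c(msg, "explainedVariance fractions must lie in [0, 1]")
    if (sum(ev) > 1 + 1e-8)
      msg <- c(msg, "explainedVariance fractions must sum to <= 1")
    if (is.unsorted(-ev, strictly = FALSE))
      msg <- c(msg, "explainedVariance fractions must be non-increasing")
  }
  if (ncol(L) >= 1) {
    G <- crossprod(L)
    if (max(abs(G - diag(ncol(L)))) > 1e-6)
      msg <- c(msg, "loading columns must be orthonormal")
  }
  if (length(msg)) msg else TRUE
})

#' Bootstrap summary of component-loading reliability
#'
#' Percentile bootstrap bounds per loading; a loading is flagged reliable
#' when its 95% interval excludes zero.
#'
#' @slot lower,upper item x component matrices of percentile bounds.
#' @slot reliable logical item x component matrix.
#' @slot nBoot bootstrap replicate count.
#' @exportClass BootstrapLoadingSummary
setClass("BootstrapLoadingSummary",
  representation(lower = "matrix", upper = "matrix",
                 reliable = "matrix", nBoot = "integer")
)

setValidity("BootstrapLoadingSummary", function(object) {
  msg <- character()
  if (!identical(dim(object@lower), dim(object@upper)) ||
      !identical(dim(object@lower), dim(object@reliable)))
    msg <- c(msg, "lower, upper and reliable must share dimensions")
  if (any(object@lower > object@upper))
    msg <- c(msg, "lower bounds must not exceed upper bounds")
  excl <- object@lower > 0 | object@upper < 0
  if (!identical(as.vector(excl), as.vector(object@reliable)))
    msg <- c(msg, "reliable flag must equal 'interval excludes zero'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Connectome containers
## ---------------------------------------------------------------------------

#' Fisher-z functional connectivity matrix
#'
#' Symmetric node x node matrix of Fisher z-transformed Pearson correlations
#' with a zero diagonal.
#'
#' @slot values symmetric numeric matrix with zero diagonal, finite entries.
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix", representation(values = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  else {
    if (any(!is.finite(v))) msg <- c(msg, "entries must be finite")
    else {
      if (max(abs(v - t(v))) > 1e-10) msg <- c(msg, "values must be symmetric")
      if (max(abs(diag(v))) > 1e-12) msg <- c(msg, "diagonal must be zero")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ConnectivityMatrix
#'
#' @param values symmetric numeric matrix with zero diagonal.
#' @return A [ConnectivityMatrix-class] object.
#' @export
ConnectivityMatrix <- function(values) {
  new("ConnectivityMatrix", values = as.matrix(values))
}

#' Parcellated time-series run
#'
#' One scanning run: node time courses plus the raw confound inputs needed to
#' build the nuisance design (6 base motion parameters, tissue/global means)
#' and the run's motion summary for QC.
#'
#' @slot series node x frame numeric matrix.
#' @slot motionParams frame x 6 base motion parameters.
#' @slot tissue frame x k tissue/global mean signals (may have 0 columns).
#' @slot motion one-row data.frame motion summary (see [generateMotion()]).
#' @exportClass TimeSeriesRun
setClass("TimeSeriesRun",
  representation(series = "matrix", motionParams = "matrix",
                 tissue = "matrix", motion = "data.frame")
)

setValidity("TimeSeriesRun", function(object) {
  msg <- character()
  nf <- ncol(object@series)
  if (nf < 2L) msg <- c(msg, "a run needs at least 2 frames")
  if (nrow(object@motionParams) != nf)
    msg <- c(msg, "motionParams must have one row per frame")
  if (ncol(object@motionParams) != 6L)
    msg <- c(msg, "motionParams must have 6 base columns")
  if (nrow(object@tissue) && nrow(object@tissue) != nf)
    msg <- c(msg, "tissue must have one row per frame")
  if (length(msg)) msg else TRUE
})

#' Construct a TimeSeriesRun
#'
#' @param series node x frame matrix.
#' @param motionParams frame x 6 base motion parameters (3 translations,
#'   3 rotations).
#' @param tissue optional frame x k tissue/global signals.
#' @param motion optional one-row motion-summary data.frame.
#' @return A [TimeSeriesRun-class] object.
#' @export
TimeSeriesRun <- function(series, motionParams,
                          tissue = matrix(0, ncol(series), 0),
                          motion = data.frame()) {
  new("TimeSeriesRun", series = as.matrix(series),
      motionParams = as.matrix(motionParams),
      tissue = as.matrix(tissue), motion = motion)
}

#' Motion quality-control thresholds
#'
#' Runs exceeding any threshold (strictly) are excluded: more than 0.15 mm
#' mean frame-to-frame displacement, 2 mm maximum displacement, or more than
#' 3 degrees of rotation.
#'
#' @slot maxMeanFfd mm.
#' @slot maxDisplacement mm.
#' @slot maxRotation degrees.
#' @exportClass QcThresholds
setClass("QcThresholds",
  representation(maxMeanFfd = "numeric", maxDisplacement = "numeric",
                 maxRotation = "numeric")
)

setValidity("QcThresholds", function(object) {
  if (any(c(object@maxMeanFfd, object@maxDisplacement, object@maxRotation) <= 0))
    "all thresholds must be positive" else TRUE
})

#' Construct QC thresholds
#'
#' @param maxMeanFfd mean frame-to-frame displacement limit (mm).
#' @param maxDisplacement maximum displacement limit (mm).
#' @param maxRotation maximum rotation limit (degrees).
#' @return A [QcThresholds-class] object.
#' @export
QcThresholds <- function(maxMeanFfd = 0.15, maxDisplacement = 2,
                         maxRotation = 3) {
  new("QcThresholds", maxMeanFfd = maxMeanFfd,
      maxDisplacement = maxDisplacement, maxRotation = maxRotation)
}

## ---------------------------------------------------------------------------
## Prediction containers
## ---------------------------------------------------------------------------

#' Ridge regression model on standardized edge features
#'
#' @slot coefficients per-feature weights (on the standardized scale).
#' @slot intercept training mean of the outcome (intercept unpenalized).
#' @slot alpha L2 penalty (>= 0).
#' @slot featureCenter,featureScale training-set standardization parameters.
#' @slot selected integer indices of the features the model was fitted on,
#'   relative to the full feature space (length 0 when all were used).
#' @exportClass RidgeModel
setClass("RidgeModel",
  representation(coefficients = "numeric", intercept = "numeric",
                 alpha = "numeric", featureCenter = "numeric",
                 featureScale = "numeric", selected = "integer")
)

setValidity("RidgeModel", function(object) {
  msg <- character()
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  n <- length(object@coefficients)
  if (length(object@featureCenter) && length(object@featureCenter) != n)
    msg <- c(msg, "featureCenter must match coefficient length")
  if (length(object@featureScale)) {
    if (length(object@featureScale) != n)
      msg <- c(msg, "featureScale must match coefficient length")
    if (any(object@featureScale < 0))
      msg <- c(msg, "featureScale must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-validated prediction result
#'
#' Out-of-fold predictions (each subject predicted exactly once), the fold
#' assignment, and the per-fold ridge models with their tuned alphas.
#'
#' @slot predicted,observed per-subject scores.
#' @slot folds integer fold id per subject (1..k).
#' @slot models list of [RidgeModel-class], one per fold.
#' @slot nFeatures width of the full feature space.
#' @slot condition condition label (e.g. "rest", "MID", "combined").
#' @exportClass CvPrediction
setClass("CvPrediction",
  representation(predicted = "numeric", observed = "numeric",
                 folds = "integer", models = "list",
                 nFeatures = "integer", condition = "character")
)

setValidity("CvPrediction", function(object) {
  msg <- character()
  n <- length(object@predicted)
  if (length(object@observed) != n || length(object@folds) != n)
    msg <- c(msg, "predicted, observed and folds must share length")
  if (length(object@models) != max(object@folds))
    msg <- c(msg, "one model per fold required")
  if (any(!is.finite(object@predicted)))
    msg <- c(msg, "every subject must be predicted exactly once")
  if (length(msg)) msg else TRUE
})

#' Covariate-adjusted performance estimate
#'
#' Partial correlation between predicted and observed scores with a
#' percentile bootstrap confidence interval.
#'
#' @slot rp partial correlation (between -1 and 1).
#' @slot ciLow,ciHigh percentile bootstrap 95% bounds.
#' @slot nBoot bootstrap replicate count.
#' @slot covariates covariate labels adjusted for.
#' @exportClass PerformanceEstimate
setClass("PerformanceEstimate",
  representation(rp = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 nBoot = "integer", covariates = "character")
)

setValidity("PerformanceEstimate", function(object) {
  msg <- character()
  if (abs(object@rp) > 1 + 1e-12) msg <- c(msg, "rp must lie in [-1, 1]")
  if (object@ciLow > object@ciHigh) msg <- c(msg, "ciLow must be <= ciHigh")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Characterization containers
## ---------------------------------------------------------------------------

#' Node-to-network atlas
#'
#' Assigns every node of the parcellation to exactly one functional network
#' (e.g. medial-frontal, frontoparietal, default-mode, motor, visual,
#' subcortical-cerebellum).
#'
#' @slot network character network label per node.
#' @exportClass NetworkAtlas
setClass("NetworkAtlas", representation(network = "character"))

setValidity("NetworkAtlas", function(object) {
  if (length(object@network) < 2L) return("atlas needs >= 2 nodes")
  if (anyNA(object@network) || any(!nzchar(object@network)))
    return("every node must carry a non-empty network label")
  TRUE
})

#' Construct a NetworkAtlas
#'
#' @param network character vector of network labels, one per node.
#' @return A [NetworkAtlas-class] object.
#' @export
NetworkAtlas <- function(network) {
  new("NetworkAtlas", network = as.character(network))
}

#' Network-pair summary of a model's most informative edges
#'
#' @slot edges data.frame of selected edges: nodeI, nodeJ (i < j),
#'   coefficient, networkI, networkJ.
#' @slot pairSummary data.frame per unordered network pair: networkA,
#'   networkB, count, totalAbsCoefficient.
#' @slot fraction selection fraction used.
#' @exportClass EdgeNetworkSummary
setClass("EdgeNetworkSummary",
  representation(edges = "data.frame", pairSummary = "data.frame",
                 fraction = "numeric")
)

setValidity("EdgeNetworkSummary", function(object) {
  msg <- character()
  if (nrow(object@edges) && any(object@edges$nodeI >= object@edges$nodeJ))
    msg <- c(msg, "edges must satisfy nodeI < nodeJ")
  if (sum(object@pairSummary$count) != nrow(object@edges))
    msg <- c(msg, "network-pair counts must sum to the number of edges")
  if (length(msg)) msg else TRUE
})
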