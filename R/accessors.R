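## Generics --------------------------------------------------------------

#' @name cpmrisk-accessors
#' @title Accessors for cpmrisk classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object an object of the documented class.
#' @param x an object of the documented class.
#' @return The accessed component.
NULL

#' @rdname cpmrisk-accessors
#' @export
setGeneric("responseValues", function(object) standardGeneric("responseValues"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("itemInfo", function(object) standardGeneric("itemInfo"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("itemNames", function(object) standardGeneric("itemNames"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("componentLoadings", function(object) standardGeneric("componentLoadings"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("transformParams", function(object) standardGeneric("transformParams"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("connMatrix", function(object) standardGeneric("connMatrix"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("predictedScores", function(object) standardGeneric("predictedScores"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("observedScores", function(object) standardGeneric("observedScores"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("foldAssignment", function(object) standardGeneric("foldAssignment"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("foldModels", function(object) standardGeneric("foldModels"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("foldAlphas", function(object) standardGeneric("foldAlphas"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("rpEstimate", function(object) standardGeneric("rpEstimate"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("reliableLoadings", function(object) standardGeneric("reliableLoadings"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("loadingBounds", function(object) standardGeneric("loadingBounds"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("networkLabels", function(object) standardGeneric("networkLabels"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))
#' @rdname cpmrisk-accessors
#' @export
setGeneric("pairSummary", function(object) standardGeneric("pairSummary"))

## Methods ---------------------------------------------------------------

#' @rdname cpmrisk-accessors
setMethod("responseValues", "ItemResponseTable", function(object) object@values)
#' @rdname cpmrisk-accessors
setMethod("itemInfo", "ItemResponseTable", function(object) object@itemInfo)
#' @rdname cpmrisk-accessors
setMethod("subjectIds", "ItemResponseTable", function(object) rownames(object@values))
#' @rdname cpmrisk-accessors
setMethod("itemNames", "ItemResponseTable", function(object) colnames(object@values))
#' @rdname cpmrisk-accessors
setMethod("itemNames", "ComponentModel", function(object) rownames(object@loadings))

#' @rdname cpmrisk-accessors
setMethod("componentLoadings", "ComponentModel", function(object) object@loadings)
#' @rdname cpmrisk-accessors
setMethod("explainedVariance", "ComponentModel", function(object) object@explainedVariance)
#' @rdname cpmrisk-accessors
setMethod("nComponents", "ComponentModel", function(object) object@nComponents)
#' @rdname cpmrisk-accessors
setMethod("transformParams", "ComponentModel", function(object) object@transform)

#' @rdname cpmrisk-accessors
setMethod("connMatrix", "ConnectivityMatrix", function(object) object@values)
#' @rdname cpmrisk-accessors
setMethod("nNodes", "ConnectivityMatrix", function(object) nrow(object@values))
#' @rdname cpmrisk-accessors
setMethod("nNodes", "NetworkAtlas", function(object) length(object@network))

#' @rdname cpmrisk-accessors
setMethod("predictedScores", "CvPrediction", function(object) object@predicted)
#' @rdname cpmrisk-accessors
setMethod("observedScores", "CvPrediction", function(object) object@observed)
#' @rdname cpmrisk-accessors
setMethod("foldAssignment", "CvPrediction", function(object) object@folds)
#' @rdname cpmrisk-accessors
setMethod("foldModels", "CvPrediction", function(object) object@models)
#' @rdname cpmrisk-accessors
setMethod("foldAlphas", "CvPrediction", function(object)
  vapply(object@models, function(m) m@alpha, numeric(1)))

#' @rdname cpmrisk-accessors
setMethod("rpEstimate", "PerformanceEstimate", function(object) object@rp)
#' @rdname cpmrisk-accessors
setMethod("confInt", "PerformanceEstimate", function(object)
  c(lower = object@ciLow, upper = object@ciHigh))

#' @rdname cpmrisk-accessors
setMethod("reliableLoadings", "BootstrapLoadingSummary", function(object) object@reliable)
#' @rdname cpmrisk-accessors
setMethod("loadingBounds", "BootstrapLoadingSummary", function(object)
  list(lower = object@lower, upper = object@upper))

#' @rdname cpmrisk-accessors
setMethod("networkLabels", "NetworkAtlas", function(object) object@network)
#' @rdname cpmrisk-accessors
setMethod("edgeTable", "EdgeNetworkSummary", function(object) object@edges)
#' @rdname cpmrisk-accessors
setMethod("pairSummary", "EdgeNetworkSummary", function(object) object@pairSummary)

## dim helpers
#' @rdname cpmrisk-accessors
#' @export
setMethod("dim", "ItemResponseTable", function(x) dim(x@values))

## Show methods ----------------------------------------------------------

setMethod("show", "ItemResponseTable", function(object) {
  cat(sprintf("ItemResponseTable: %d subjects x %d items\n",
              nrow(object@values), ncol(object@values)))
  cat("  items:", paste(utils::head(colnames(object@values), 6), collapse = ", "),
      if (ncol(object@values) > 6) "..." else "", "\n")
})

setMethod("show", "FactorSpec", function(object) {
  cat(sprintf("FactorSpec: %d items, %d factors; skew severity in [%.2g, %.2g]\n",
              nrow(object@itemLoadings), ncol(object@itemLoadings),
              min(object@skewSeverity), max(object@skewSeverity)))
})

setMethod("show", "ConnectomeSignalSpec", function(object) {
  cat(sprintf(
    "ConnectomeSignalSpec: %d nodes (%d edges), %d signal edges, effect size %s\n",
    object@nNodes, object@nNodes * (object@nNodes - 1L) / 2L,
    length(object@signalEdges),
    paste(format(unique(object@effectSize), digits = 3), collapse = "/")))
})

setMethod("show", "ComponentModel", function(object) {
  cat(sprintf("ComponentModel: %d items, %d components\n",
              nrow(object@loadings), object@nComponents))
  ev <- object@explainedVariance
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * utils::head(ev, 5)), collapse = ", "),
      if (length(ev) > 5) "..." else "", "\n")
})

setMethod("show", "TransformParams", function(object) {
  cat(sprintf("TransformParams for %d items (Yeo-Johnson lambda + z-scaling)\n",
              length(object@lambda)))
})

setMethod("show", "BootstrapLoadingSummary", function(object) {
  cat(sprintf(
    "BootstrapLoadingSummary: %d items x %d components, %d bootstraps; %d/%d loadings reliable\n",
    nrow(object@lower), ncol(object@lower), object@nBoot,
    sum(object@reliable), length(object@reliable)))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  n <- nrow(object@values)
  cat(sprintf("ConnectivityMatrix: %d nodes, %d unique edges (Fisher z)\n",
              n, n * (n - 1L) / 2L))
})

setMethod("show", "TimeSeriesRun", function(object) {
  cat(sprintf("TimeSeriesRun: %d nodes x %d frames, %d tissue regressors\n",
              nrow(object@series), ncol(object@series), ncol(object@tissue)))
})

setMethod("show", "QcThresholds", function(object) {
  cat(sprintf(
    "QcThresholds: mean FFD > %.3g mm | max displacement > %.3g mm | max rotation > %.3g deg => exclude\n",
    object@maxMeanFfd, object@maxDisplacement, object@maxRotation))
})

setMethod("show", "RidgeModel", function(object) {
  cat(sprintf("RidgeModel: %d features, alpha = %.4g, intercept = %.4g\n",
              length(object@coefficients), object@alpha, object@intercept))
})

setMethod("show", "CvPrediction", function(object) {
  r <- stats::cor(object@predicted, object@observed)
  cat(sprintf(
    "CvPrediction [%s]: %d subjects, %d folds; out-of-fold r = %.3f\n",
    object@condition, length(object@predicted), max(object@folds), r))
})

setMethod("show", "PerformanceEstimate", function(object) {
  cat(sprintf("PerformanceEstimate: r_p = %.3f, 95%% CI [%.3f, %.3f] (%d bootstraps)\n",
              object@rp, object@ciLow, object@ciHigh, object@nBoot))
  if (length(object@covariates))
    cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
})

setMethod("show", "NetworkAtlas", function(object) {
  tb <- table(object@network)
  cat(sprintf("NetworkAtlas: %d nodes, %d networks (%s)\n",
              length(object@network), length(tb),
              paste(names(tb), collapse = ", ")))
})

setMethod("show", "EdgeNetworkSummary", function(object) {
  cat(sprintf("EdgeNetworkSummary: %d edges (top %.2g%%), %d network pairs\n",
              nrow(object@edges), 100 * object@fraction, nrow(object@pairSummary)))
})
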