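# Accessor generics and show methods.

#' Extract the feature matrix (features x bins) of a BinnedFeatures
#' @param x a \linkS4class{BinnedFeatures}
#' @return numeric matrix, one row per feature, one column per 15-ms bin
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "BinnedFeatures", function(x)
  SummarizedExperiment::assay(x, "features"))

#' Bin timestamps (s) of a BinnedFeatures
#' @param x a \linkS4class{BinnedFeatures}
#' @export
setGeneric("binTimes", function(x) standardGeneric("binTimes"))

#' @rdname binTimes
#' @export
setMethod("binTimes", "BinnedFeatures", function(x)
  SummarizedExperiment::colData(x)$timestamp)

#' Feature family ("spike"/"hfp") per row of a BinnedFeatures
#' @param x a \linkS4class{BinnedFeatures}
#' @export
setGeneric("featureFamily", function(x) standardGeneric("featureFamily"))

#' @rdname featureFamily
#' @export
setMethod("featureFamily", "BinnedFeatures", function(x)
  as.character(SummarizedExperiment::rowData(x)$family))

#' Per-feature baseline currently attached to a BinnedFeatures
#' @param x a \linkS4class{BinnedFeatures}
#' @export
setGeneric("baselineValues", function(x) standardGeneric("baselineValues"))

#' @rdname baselineValues
#' @export
setMethod("baselineValues", "BinnedFeatures", function(x)
  SummarizedExperiment::rowData(x)$baseline)

#' Replace the per-feature baseline of a BinnedFeatures
#' @param x a \linkS4class{BinnedFeatures}
#' @param value numeric vector, one entry per feature row
#' @export
setGeneric("baselineValues<-",
           function(x, value) standardGeneric("baselineValues<-"))

#' @rdname baselineValues-set
#' @export
setMethod("baselineValues<-", "BinnedFeatures", function(x, value) {
  stopifnot(length(value) == nrow(x), all(is.finite(value)))
  SummarizedExperiment::rowData(x)$baseline <- value
  x
})

#' Intent labels (vx, vy, click) attached to a BinnedFeatures, or NULL
#' @param x a \linkS4class{BinnedFeatures}
#' @export
setGeneric("intentLabels", function(x) standardGeneric("intentLabels"))

#' @rdname intentLabels
#' @export
setMethod("intentLabels", "BinnedFeatures", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!all(c("intentVx", "intentVy", "clickIntent") %in% colnames(cd)))
    return(NULL)
  data.frame(vx = cd$intentVx, vy = cd$intentVy, click = cd$clickIntent)
})

#' Number of channels of a synthetic participant
#' @param x a \linkS4class{SyntheticParticipant}
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname nChannels
#' @export
setMethod("nChannels", "SyntheticParticipant", function(x) x@nChannels)

#' Ground-truth preferred directions (radians) of a synthetic participant
#' @param x a \linkS4class{SyntheticParticipant}
#' @export
setGeneric("preferredDirections",
           function(x) standardGeneric("preferredDirections"))

#' @rdname preferredDirections
#' @export
setMethod("preferredDirections", "SyntheticParticipant",
          function(x) x@preferredDirection)

#' Targets table of a TaskLayout
#' @param x a \linkS4class{TaskLayout}
#' @export
setGeneric("layoutTargets", function(x) standardGeneric("layoutTargets"))

#' @rdname layoutTargets
#' @export
setMethod("layoutTargets", "TaskLayout", function(x) x@targets)

#' Workspace bounds c(xmin, ymin, xmax, ymax) of a TaskLayout
#' @param x a \linkS4class{TaskLayout}
#' @export
setGeneric("layoutBounds", function(x) standardGeneric("layoutBounds"))

#' @rdname layoutBounds
#' @export
setMethod("layoutBounds", "TaskLayout", function(x) x@bounds)

#' Current bias estimate (2-vector, units/s)
#' @param x a \linkS4class{BiasState}
#' @export
setGeneric("biasEstimate", function(x) standardGeneric("biasEstimate"))

#' @rdname biasEstimate
#' @export
setMethod("biasEstimate", "BiasState", function(x) x@B)

setMethod("show", "SyntheticParticipant", function(object) {
  cat("SyntheticParticipant:", object@nChannels, "channels,",
      object@noiseModel, "noise\n")
  cat("  mean baseline", round(mean(object@baselineRate), 2),
      "counts/bin; mean depth", round(mean(object@modulationDepth), 2),
      "counts/bin per unit speed\n")
  cat("  drift sigma", object@driftSigma, "theta", object@driftTheta,
      "; seed", object@seed, "\n")
})

setMethod("show", "KalmanDecoder", function(object) {
  cat("KalmanDecoder:", length(object@selectedFeatures),
      "features, decay", object@decay,
      ", bin", object@binWidth * 1000, "ms\n")
})

setMethod("show", "ClickHMM", function(object) {
  cat("ClickHMM: 2 states over", ncol(object@rotation), "PCs of",
      length(object@featureIndex), "features; threshold",
      ifelse(is.na(object@clickThreshold), "uncalibrated",
             signif(object@clickThreshold, 4)), "\n")
})

setMethod("show", "TaskLayout", function(object) {
  cat("TaskLayout", object@layoutKind, "with", nrow(object@targets),
      "targets in [", paste(signif(object@bounds, 3), collapse = ", "), "]\n")
})

setMethod("show", "BiasState", function(object) {
  cat("BiasState: B = (", paste(signif(object@B, 4), collapse = ", "),
      "), tau =", object@tau, "s, gate =", signif(object@speedThreshold, 4),
      "\n")
})
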