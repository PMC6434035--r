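#' Total scheduled scan duration
#'
#' @param x a [Paradigm-class]
#' @return duration in seconds, including the calibration period
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' @rdname totalDuration
#' @export
setMethod("totalDuration", "Paradigm", function(x) {
  x@calibrationS + functionalDuration(x)
})

#' Functional (post-calibration) scan duration
#'
#' @param x a [Paradigm-class]
#' @return duration in seconds of the retained functional frames
#' @export
setGeneric("functionalDuration", function(x) standardGeneric("functionalDuration"))

#' @rdname functionalDuration
#' @export
setMethod("functionalDuration", "Paradigm", function(x) {
  x@leadInS + x@nCycles * (x@bhS + x@recoveryS + x@pacedS) + x@tailS
})

#' Number of retained functional frames
#'
#' @param x a [Paradigm-class], [VoxelSeries-class] or
#'   [MultiEchoSeries-class]
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Paradigm", function(x) {
  as.integer(round(functionalDuration(x) / x@trS))
})

#' @rdname nFrames
#' @export
setMethod("nFrames", "VoxelSeries", function(x) dim(x@data)[4])

#' @rdname nFrames
#' @export
setMethod("nFrames", "MultiEchoSeries", function(x) dim(x@data)[4])

#' Lag shifts of a regressor bank
#'
#' @param x a [RegressorBank-class]
#' @return numeric vector of shifts in seconds
#' @export
setGeneric("shifts", function(x) standardGeneric("shifts"))

#' @rdname shifts
#' @export
setMethod("shifts", "RegressorBank", function(x) x@shiftsS)

#' Extract the voxel data array
#'
#' @param x a series, map or mask container
#' @param ... unused
#' @return the underlying numeric array
#' @export
setGeneric("seriesData", function(x, ...) standardGeneric("seriesData"))

#' @rdname seriesData
#' @export
setMethod("seriesData", "VoxelSeries", function(x, ...) x@data)

#' @rdname seriesData
#' @param echo for multi-echo input, the echo to extract (NULL for all)
#' @export
setMethod("seriesData", "MultiEchoSeries", function(x, echo = NULL, ...) {
  if (is.null(echo)) return(x@data)
  .echo_array(x, echo)
})

#' Number of echoes in a multi-echo series
#'
#' @param x a [MultiEchoSeries-class]
#' @return integer echo count
#' @export
setGeneric("nEchoes", function(x) standardGeneric("nEchoes"))

#' @rdname nEchoes
#' @export
setMethod("nEchoes", "MultiEchoSeries", function(x) dim(x@data)[5])

#' Echo times
#'
#' @param x a [MultiEchoSeries-class] or [EchoWeights-class]
#' @return echo times in milliseconds
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))

#' @rdname echoTimes
#' @export
setMethod("echoTimes", "MultiEchoSeries", function(x) x@teMs)

#' @rdname echoTimes
#' @export
setMethod("echoTimes", "EchoWeights", function(x) x@teMs)

setMethod("show", "Paradigm", function(object) {
  cat("Paradigm:", object@nCycles, "x", object@bhS, "s breath-hold cycles\n")
  cat(sprintf("  lead-in %g s | recovery %g s | paced %g s | tail %g s | calibration %g s\n",
              object@leadInS, object@recoveryS, object@pacedS, object@tailS,
              object@calibrationS))
  cat(sprintf("  TR %g s | total %g s | %d functional frames\n",
              object@trS, totalDuration(object), nFrames(object)))
})

setMethod("show", "RegressorBank", function(object) {
  cat(sprintf("RegressorBank: %d shifts (%g to %g s) x %d frames\n",
              length(object@shiftsS), min(object@shiftsS), max(object@shiftsS),
              ncol(object@regressors)))
})

setMethod("show", "MultiEchoSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("MultiEchoSeries: %d x %d x %d grid, %d frames, %d echoes\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  TE %s ms | TR %g s | %s\n",
              paste(object@teMs, collapse = "/"), object@trS,
              object@labelParity))
})

setMethod("show", "VoxelSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d grid, %d frames, TR %g s\n",
              class(object), d[1], d[2], d[3], d[4], object@trS))
})

setMethod("show", "ActivationResult", function(object) {
  n <- sum(object@mask)
  cat(sprintf("ActivationResult: %d voxels in mask, dof = %g\n", n, object@dof))
  cat(sprintf("  active at p < %g: %d | unreliable lag: %d\n",
              object@pThreshold, sum(object@activeMask, na.rm = TRUE),
              sum(!object@reliableLag & object@mask, na.rm = TRUE)))
})

setMethod("show", "CvrMMaps", function(object) {
  cat(sprintf("CvrMMaps (alpha = %g, beta = %g): %d valid voxels\n",
              object@alpha, object@beta, sum(object@validMask)))
  cat(sprintf("  median CVR %.3g%% | median CBF ratio %.3g | median M %.3g%%\n",
              stats::median(object@cvrPct[object@validMask]),
              stats::median(object@cbfRatio[object@validMask]),
              stats::median(object@mPct[object@validMask])))
})

setMethod("show", "RetestReport", function(object) {
  cat(sprintf("RetestReport: Dice %.3f | repeatability %.3f | r %.3f (z %.3f)\n",
              object@dice, object@repeatability, object@pearsonR,
              object@fisherZ))
  cat(sprintf("  active TP1/TP2: %d/%d | overlap %d | excluded voxels %d\n",
              object@nActive1, object@nActive2,
              sum(object@overlapMask), object@repeatabilityExcluded))
})
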