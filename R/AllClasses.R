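#' @import methods
NULL

#' Breath-hold paradigm schedule
#'
#' Encodes the timing of a breath-hold (BH) acquisition: an initial block of
#' calibration frames (discarded before analysis), a paced-breathing lead-in,
#' `nCycles` cycles of breath-hold / self-paced recovery / paced breathing,
#' and a final paced tail. All durations are in seconds. The functional part
#' of the scan (total minus calibration) must tile exactly into repetition
#' times; use [buildParadigm()] to construct validated objects.
#'
#' @slot leadInS seconds of paced breathing before the first breath-hold
#' @slot nCycles number of breath-hold cycles
#' @slot bhS breath-hold duration per cycle (s)
#' @slot recoveryS self-paced recovery duration per cycle (s)
#' @slot pacedS paced breathing duration per cycle (s)
#' @slot tailS final paced-breathing duration (s)
#' @slot calibrationS calibration period at the start of the scan (s),
#'   discarded before analysis
#' @slot trS repetition time (s)
#' @export
setClass("Paradigm", representation(
  leadInS = "numeric", nCycles = "integer", bhS = "numeric",
  recoveryS = "numeric", pacedS = "numeric", tailS = "numeric",
  calibrationS = "numeric", trS = "numeric"
))

setValidity("Paradigm", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  for (s in c("leadInS", "bhS", "recoveryS", "pacedS", "tailS",
              "calibrationS", "trS")) {
    if (!num1(slot(object, s))) msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg)) return(msg)
  if (object@trS <= 0) msg <- c(msg, "trS must be > 0")
  if (object@nCycles < 0L) msg <- c(msg, "nCycles must be >= 0")
  if (object@nCycles > 0L && (object@bhS <= 0 || object@recoveryS < 0 || object@pacedS < 0))
    msg <- c(msg, "cycle durations must be positive when nCycles > 0")
  if (object@leadInS < 0 || object@tailS < 0 || object@calibrationS < 0)
    msg <- c(msg, "leadInS, tailS and calibrationS must be >= 0")
  if (!length(msg)) {
    fd <- functionalDuration(object)
    nf <- fd / object@trS
    if (abs(nf - round(nf)) > 1e-8)
      msg <- c(msg, sprintf(
        "functional duration %.4g s (total minus calibrationS) is not an integer multiple of trS = %.4g s",
        fd, object@trS))
  }
  if (length(msg)) msg else TRUE
})

#' Bank of lag-shifted breath-hold regressors
#'
#' Rows are unit-peak, HRF-convolved breath-hold responses time-shifted by
#' `shiftsS` seconds and sampled on the functional frame grid. Built by
#' [buildRegressorBank()].
#'
#' @slot shiftsS ordered vector of time shifts (s), multiples of the TR
#' @slot regressors numeric matrix, `length(shiftsS)` rows by frame count
#'   columns
#' @slot hrfParams list of double-gamma HRF parameters
#' @slot fineDt fine-grid sampling step used for the convolution (s)
#' @slot paradigm the [Paradigm-class] the bank was built from
#' @export
setClass("RegressorBank", representation(
  shiftsS = "numeric", regressors = "matrix", hrfParams = "list",
  fineDt = "numeric", paradigm = "Paradigm"
))

setValidity("RegressorBank", function(object) {
  msg <- character()
  if (nrow(object@regressors) != length(object@shiftsS))
    msg <- c(msg, "number of regressor rows must match length(shiftsS)")
  if (is.unsorted(object@shiftsS, strictly = TRUE))
    msg <- c(msg, "shiftsS must be strictly increasing")
  if (!all(is.finite(object@regressors)))
    msg <- c(msg, "regressors must be finite")
  if (length(msg)) msg else TRUE
})

#' Single 4-D voxel time series
#'
#' A plain 4-D (x, y, z, frame) signal array with acquisition metadata.
#' Used for echo-combined BOLD data and as the parent of [PwSeries-class].
#'
#' @slot data 4-D numeric array (x, y, z, frame)
#' @slot trS repetition time (s)
#' @slot labelParity `"even-control"` if 0-based even frames are ASL control
#'   frames, `"odd-control"` otherwise
#' @slot voxelSizeMm numeric length-3 voxel edge lengths (mm)
#' @export
setClass("VoxelSeries", representation(
  data = "array", trS = "numeric", labelParity = "character",
  voxelSizeMm = "numeric"
))

setValidity("VoxelSeries", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4-D array (x, y, z, frame)")
  if (!object@labelParity %in% c("even-control", "odd-control"))
    msg <- c(msg, "labelParity must be 'even-control' or 'odd-control'")
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    msg <- c(msg, "voxelSizeMm must be three positive lengths")
  if (length(msg)) msg else TRUE
})

#' Multi-echo 4-D time series
#'
#' Per-echo 4-D voxel time series stacked in a 5-D array (x, y, z, frame,
#' echo), with echo times, repetition time and the ASL label/control frame
#' parity.
#'
#' @slot data 5-D numeric array (x, y, z, frame, echo)
#' @slot teMs strictly increasing echo times (ms)
#' @slot trS repetition time (s)
#' @slot labelParity see [VoxelSeries-class]
#' @slot voxelSizeMm numeric length-3 voxel edge lengths (mm)
#' @export
setClass("MultiEchoSeries", representation(
  data = "array", teMs = "numeric", trS = "numeric",
  labelParity = "character", voxelSizeMm = "numeric"
))

setValidity("MultiEchoSeries", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 5L)
    msg <- c(msg, "data must be a 5-D array (x, y, z, frame, echo)")
  else if (d[5] != length(object@teMs))
    msg <- c(msg, "fifth dimension must match length(teMs)")
  if (any(object@teMs <= 0) || is.unsorted(object@teMs, strictly = TRUE))
    msg <- c(msg, "teMs must be strictly increasing and positive")
  if (!object@labelParity %in% c("even-control", "odd-control"))
    msg <- c(msg, "labelParity must be 'even-control' or 'odd-control'")
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    msg <- c(msg, "voxelSizeMm must be three positive lengths")
  if (length(msg)) msg else TRUE
})

#' Perfusion-weighted series
#'
#' Output of [pwFromEcho1()]: the first-echo series high-pass filtered and
#' demodulated by the label/control alternation. Positive values mean
#' control exceeds label signal.
#'
#' @slot sourceEcho index of the echo the series was derived from
#' @slot cutoffHz high-pass cutoff frequency (Hz)
#' @slot filterOrder Butterworth filter order
#' @export
setClass("PwSeries", contains = "VoxelSeries", representation(
  sourceEcho = "integer", cutoffHz = "numeric", filterOrder = "integer"
))

#' Voxelwise T2* fit
#'
#' Result of [fitT2Star()]: log-linear fit of the frame-mean signal decay
#' across echoes, S(TE) = S0 * exp(-TE / T2*).
#'
#' @slot t2starMs 3-D array of T2* (ms); NA where invalid
#' @slot s0 3-D array of extrapolated zero-TE signal; NA where invalid
#' @slot validMask logical 3-D array of voxels with an admissible fit
#' @export
setClass("T2StarMap", representation(
  t2starMs = "array", s0 = "array", validMask = "array"
))

#' Per-voxel echo-combination weights
#'
#' T2*-weighted combination weights, w_e proportional to
#' TE_e * exp(-TE_e / T2*), normalised to sum to one per voxel. Voxels
#' without a valid T2* fit fall back to uniform weights and are flagged.
#'
#' @slot w 4-D array (x, y, z, echo) of weights
#' @slot teMs echo times the weights refer to (ms)
#' @slot validMask logical 3-D array; FALSE where uniform fallback was used
#' @export
setClass("EchoWeights", representation(
  w = "array", teMs = "numeric", validMask = "array"
))

#' Ground truth for the multi-echo digital phantom
#'
#' Holds every quantity the synthetic generator needs and the downstream
#' pipeline is expected to recover: tissue masks, baseline signal and T2*,
#' voxelwise breath-hold response lag, fractional BOLD change at the
#' reference TE, CBF ratio during breath-hold, perfusion (label/control)
#' amplitude, and the noise model.
#'
#' @slot gmMask,wmMask disjoint logical 3-D tissue masks
#' @slot s0Map baseline zero-TE signal (arbitrary units)
#' @slot t2starMs baseline T2* (ms)
#' @slot lagS breath-hold response lag per voxel (s, multiples of the TR)
#' @slot cvr fractional BOLD signal change at the reference TE at the
#'   response peak (e.g. 0.017 for 1.7 percent)
#' @slot cbfRatio CBF / CBF0 at the response peak
#' @slot perfusionAmp label/control alternation amplitude, in the same
#'   units as `s0Map` (the control-minus-label difference at TE = 0 is
#'   twice this value)
#' @slot referenceTeMs TE at which `cvr` is defined (ms)
#' @slot noiseSd additive Gaussian noise standard deviation per echo
#' @slot arCoef AR(1) coefficient of the noise (0 for white noise)
#' @slot voxelSizeMm voxel edge lengths (mm)
#' @slot seed RNG seed used by [generatePhantom()]
#' @export
setClass("PhantomTruth", representation(
  gmMask = "array", wmMask = "array", s0Map = "array", t2starMs = "array",
  lagS = "array", cvr = "array", cbfRatio = "array", perfusionAmp = "array",
  referenceTeMs = "numeric", noiseSd = "numeric", arCoef = "numeric",
  voxelSizeMm = "numeric", seed = "integer"
))

setValidity("PhantomTruth", function(object) {
  msg <- character()
  d <- dim(object@gmMask)
  for (s in c("wmMask", "s0Map", "t2starMs", "lagS", "cvr", "cbfRatio",
              "perfusionAmp")) {
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, sprintf("'%s' must share the grid of gmMask", s))
  }
  if (any(object@gmMask & object@wmMask))
    msg <- c(msg, "gmMask and wmMask must be disjoint")
  if (any(object@t2starMs <= 0))
    msg <- c(msg, "t2starMs must be positive everywhere")
  if (any(object@cbfRatio <= 0))
    msg <- c(msg, "cbfRatio must be positive everywhere")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (abs(object@arCoef) >= 1) msg <- c(msg, "arCoef must lie in (-1, 1)")
  if (length(msg)) msg else TRUE
})

#' Lag-optimised breath-hold activation result
#'
#' Per-voxel output of [lagSweep()]: the GLM fit at the lag shift with the
#' highest positive t-score. `reliableLag` is FALSE where no shift produced
#' a positive t (the maximal-t fit is still reported). `dof` is the residual
#' degrees of freedom of the single chosen design, uncorrected for the lag
#' selection.
#'
#' @slot beta response amplitude at the chosen lag (signal units; the
#'   regressor is unit-peak scaled so this is the peak response)
#' @slot tstat t-score of the response
#' @slot lagS chosen lag shift (s)
#' @slot r2 variance explained by the response after nuisance projection
#' @slot intercept GLM intercept (baseline signal estimate)
#' @slot dof residual degrees of freedom
#' @slot fitted 4-D model prediction at the chosen lag
#' @slot reliableLag logical; FALSE where no positive t-score was found
#' @slot activeMask logical; t above the one-sided `pThreshold` quantile
#' @slot pThreshold the threshold used for `activeMask`
#' @slot mask analysis mask the fit was restricted to
#' @export
setClass("ActivationResult", representation(
  beta = "array", tstat = "array", lagS = "array", r2 = "array",
  intercept = "array", dof = "numeric", fitted = "array",
  reliableLag = "array", activeMask = "array", pThreshold = "numeric",
  mask = "array"
))

#' CVR, CBF-ratio and Davis-model M maps
#'
#' @slot cvrPct percent BOLD signal change per unit peak response
#' @slot cbfRatio CBF / CBF0 during breath-hold (from the PW data)
#' @slot mPct Davis-model maximum BOLD signal change, percent
#' @slot validMask logical; FALSE where any input was invalid
#' @slot alpha,beta Davis-model constants used
#' @export
setClass("CvrMMaps", representation(
  cvrPct = "array", cbfRatio = "array", mPct = "array",
  validMask = "array", alpha = "numeric", beta = "numeric"
))

#' Paired-session repeatability report
#'
#' @slot dice Dice overlap of the two thresholded activation masks
#' @slot repeatability voxel-mean repeatability index (1 minus the mean
#'   absolute normalised difference)
#' @slot repeatabilityExcluded number of voxels excluded for a zero
#'   denominator
#' @slot pearsonR spatial Pearson correlation of the two maps over the mask
#' @slot fisherZ atanh-transformed correlation
#' @slot overlapMask voxels active at both time points
#' @slot nActive1,nActive2 active voxel counts at each time point
#' @export
setClass("RetestReport", representation(
  dice = "numeric", repeatability = "numeric",
  repeatabilityExcluded = "integer", pearsonR = "numeric",
  fisherZ = "numeric", overlapMask = "array",
  nActive1 = "integer", nActive2 = "integer"
))
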