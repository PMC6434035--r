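#' Baseline signal map for percent-signal-change scaling
#'
#' Two conventions: `"mean"` takes the voxel's full-series mean (the
#' plain reading of "mean signal"); `"intercept"` takes the GLM intercept
#' at the chosen lag, which estimates the signal in the absence of the
#' response and is unbiased when the response occupies a large fraction
#' of the scan (the relevant case for the PW data, where the breath-hold
#' change is tens of percent).
#'
#' @param series the [VoxelSeries-class] that entered the GLM
#' @param result the matching [ActivationResult-class]
#' @param mode `"mean"` or `"intercept"`
#' @return 3-D baseline map
#' @export
baselineMap <- function(series, result, mode = c("mean", "intercept")) {
  mode <- match.arg(mode)
  if (mode == "intercept") return(result@intercept)
  array(colMeans(.as_frame_matrix(series@data)), dim(series@data)[1:3])
}

#' Cerebrovascular reactivity map (percent signal change)
#'
#' CVR = 100 * beta / baseline. The breath-hold regressor is unit-peak
#' scaled, so beta is the peak response amplitude and CVR the peak percent
#' signal change. Voxels with non-positive baseline are invalid (NA).
#'
#' @param beta response amplitude map (or [ActivationResult-class])
#' @param baseline baseline signal map from [baselineMap()]
#' @return 3-D CVR map in percent, NA where invalid
#' @export
cvrMap <- function(beta, baseline) {
  if (is(beta, "ActivationResult")) beta <- beta@beta
  stopifnot(identical(dim(beta), dim(baseline)))
  out <- 100 * beta / baseline
  out[!is.finite(baseline) | baseline <= 0] <- NA_real_
  out
}

#' CBF ratio during breath-hold from the PW data
#'
#' CBF / CBF0 = 1 + pwBeta / pwBaseline. Voxels with a non-positive PW
#' baseline are invalid (this mirrors the exclusion of white matter, where
#' the perfusion signal is too weak to define a baseline reliably).
#'
#' @param pwBeta PW response amplitude map (or [ActivationResult-class])
#' @param pwBaseline PW baseline map
#' @return 3-D CBF-ratio map, NA where invalid
#' @export
cbfRatioMap <- function(pwBeta, pwBaseline) {
  if (is(pwBeta, "ActivationResult")) pwBeta <- pwBeta@beta
  stopifnot(identical(dim(pwBeta), dim(pwBaseline)))
  out <- 1 + pwBeta / pwBaseline
  out[!is.finite(pwBaseline) | pwBaseline <= 0] <- NA_real_
  out
}

#' Davis-model M map
#'
#' Under a hypercapnic challenge with CMRO2 / CMRO2,0 = 1 the Davis model
#' inverts to M = (dBOLD / BOLD0) / (1 - (CBF/CBF0)^(alpha - beta)),
#' reported in percent. Voxels where the CBF ratio is non-positive or
#' equals one (singular denominator) are invalid.
#'
#' @param cvrPct percent BOLD signal change map
#' @param cbfRatio CBF / CBF0 map
#' @param alpha flow-volume coupling exponent (default 0.2)
#' @param beta susceptibility exponent (default 1)
#' @return 3-D M map in percent, NA where invalid
#' @export
mMap <- function(cvrPct, cbfRatio, alpha = 0.2, beta = 1) {
  if (alpha == beta) .stopf("alpha must differ from beta (degenerate model)")
  stopifnot(identical(dim(cvrPct), dim(cbfRatio)))
  denom <- 1 - cbfRatio^(alpha - beta)
  bad <- !is.finite(cbfRatio) | cbfRatio <= 0 | abs(denom) < 1e-12
  out <- cvrPct / denom
  out[bad] <- NA_real_
  out
}

#' Assemble CVR / CBF-ratio / M maps
#'
#' @param cvrPct,cbfRatio maps as above
#' @param alpha,beta Davis-model constants
#' @return a [CvrMMaps-class]; `validMask` marks voxels where all three
#'   maps are finite
#' @export
cvrMMaps <- function(cvrPct, cbfRatio, alpha = 0.2, beta = 1) {
  m <- mMap(cvrPct, cbfRatio, alpha = alpha, beta = beta)
  valid <- is.finite(cvrPct) & is.finite(cbfRatio) & is.finite(m)
  new("CvrMMaps", cvrPct = cvrPct, cbfRatio = cbfRatio, mPct = m,
      validMask = valid, alpha = alpha, beta = beta)
}

#' Gray/white matter contrast of a map
#'
#' Mean over the GM mask divided by the mean over the WM mask, ignoring
#' invalid (NA) voxels.
#'
#' @param map 3-D map
#' @param gmMask,wmMask nonempty logical masks
#' @return scalar contrast ratio
#' @export
gmWmContrast <- function(map, gmMask, wmMask) {
  if (!any(gmMask) || !any(wmMask)) .stopf("both tissue masks must be nonempty")
  wmMean <- mean(map[wmMask], na.rm = TRUE)
  if (!is.finite(wmMean) || wmMean == 0) .stopf("white-matter mean is zero or undefined")
  mean(map[gmMask], na.rm = TRUE) / wmMean
}
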