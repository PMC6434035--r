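#' Regress the ASL label/control alternation out of a series
#'
#' Fits each voxel time series on an intercept and the alternating
#' label/control column (+1 control, -1 label) and subtracts the
#' alternation component, leaving the series orthogonal to the (demeaned)
#' alternation regressor. Applied to BOLD data before the activation GLM;
#' the same column also appears in the GLM design, so removal here is a
#' convenience for inspection and downstream filtering.
#'
#' @param series a [VoxelSeries-class]
#' @return a [VoxelSeries-class] with the alternation removed
#' @export
regressLabelControl <- function(series) {
  stopifnot(is(series, "VoxelSeries"))
  nFr <- nFrames(series)
  if (nFr < 4L) .stopf("need at least 4 frames to regress the alternation")
  Y <- .as_frame_matrix(series@data)
  cn <- .parity_sign(nFr, series@labelParity)
  X <- cbind(1, cn)
  coefs <- solve(crossprod(X), crossprod(X, Y))
  Y <- Y - outer(cn, coefs[2L, ])
  out <- series
  out@data <- .as_series_array(Y, dim(series@data)[1:3])
  out
}

#' Polynomial detrending with the mean retained
#'
#' Projects out polynomial trends up to the given order (orthogonal
#' polynomial basis on the frame grid, i.e. discrete Legendre trends) and
#' re-adds the voxel mean so percent-signal-change baselines survive.
#' Detrending is a projection: applying it twice equals applying it once.
#'
#' @param series a [VoxelSeries-class]
#' @param order highest polynomial order to remove (default 3)
#' @return a detrended [VoxelSeries-class]
#' @export
detrendPoly <- function(series, order = 3L) {
  stopifnot(is(series, "VoxelSeries"), order >= 0L)
  nFr <- nFrames(series)
  if (nFr <= order + 1L)
    .stopf("need more than order + 1 = %d frames, have %d", order + 1L, nFr)
  Y <- .as_frame_matrix(series@data)
  mu <- colMeans(Y)
  if (order > 0L) {
    P <- stats::poly(seq_len(nFr), degree = order)  # orthogonal, demeaned
    Y <- Y - P %*% crossprod(P, Y)
  }
  out <- series
  out@data <- .as_series_array(Y, dim(series@data)[1:3])
  out
}

# Zero-phase Butterworth high-pass with mirror-reflection padding.
# Mirror (even) reflection continues the label/control alternation
# coherently across the pad boundary, so the near-Nyquist carrier sees no
# edge discontinuity.
.hp_filtfilt <- function(Y, wNorm, order = 4L) {
  bf <- signal::butter(order, wNorm, type = "high")
  n <- nrow(Y)
  npad <- min(n - 1L, 25L)
  idxL <- (npad + 1L):2L
  idxR <- (n - 1L):(n - npad)
  out <- Y
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    yp <- c(y[idxL], y, y[idxR])
    z <- signal::filtfilt(bf, yp)
    out[, j] <- z[(npad + 1L):(npad + n)]
  }
  out
}

#' Perfusion-weighted series from the first echo
#'
#' High-pass filters every voxel of the shortest-TE series (zero-phase
#' forward-backward Butterworth, default order 4 at 0.09 Hz) and
#' demodulates the result by the label/control carrier cos(pi n), signed
#' so that positive output means control exceeds label signal. The
#' alternation at the Nyquist frequency passes the filter; slow BOLD
#' fluctuations are removed before demodulation.
#'
#' @param series a [MultiEchoSeries-class] (echo 1 is used) or a
#'   [VoxelSeries-class] already containing the first-echo data
#' @param cutoffHz high-pass cutoff (Hz); must lie below the Nyquist
#'   frequency 1 / (2 TR)
#' @param filterOrder Butterworth order
#' @return a [PwSeries-class]
#' @export
pwFromEcho1 <- function(series, cutoffHz = 0.09, filterOrder = 4L) {
  if (is(series, "MultiEchoSeries")) {
    dat <- .echo_array(series, 1L)
  } else if (is(series, "VoxelSeries")) {
    dat <- series@data
  } else .stopf("series must be a MultiEchoSeries or VoxelSeries")
  nyq <- 1 / (2 * series@trS)
  if (cutoffHz >= nyq)
    .stopf("cutoff %g Hz is at or above the Nyquist frequency %g Hz",
           cutoffHz, nyq)
  nFr <- dim(dat)[4]
  Y <- .as_frame_matrix(dat)
  Y <- .hp_filtfilt(Y, cutoffHz / nyq, filterOrder)
  cn <- .parity_sign(nFr, series@labelParity)
  Y <- Y * cn
  new("PwSeries", data = .as_series_array(Y, dim(dat)[1:3]),
      trS = series@trS, labelParity = series@labelParity,
      voxelSizeMm = series@voxelSizeMm, sourceEcho = 1L,
      cutoffHz = cutoffHz, filterOrder = as.integer(filterOrder))
}

#' Pass a regressor bank through the PW filtering/demodulation operator
#'
#' The PW series is a filtered, demodulated transform of the raw signal,
#' so the breath-hold design used for the PW GLM should undergo the same
#' transform (the standard practice of filtering the design matrix with
#' the data). Each unit-peak regressor x(n) is modulated onto the
#' label/control carrier, high-pass filtered and demodulated exactly as
#' the data are; the unit-peak scaling of the underlying response is kept,
#' so the PW beta estimates the peak perfusion change.
#'
#' @param bank a [RegressorBank-class]
#' @param cutoffHz,filterOrder filter settings, matching [pwFromEcho1()]
#' @param labelParity carrier convention, matching the data
#' @return matrix of filtered regressors, same shape as `bank@regressors`
#' @export
pwRegressorBank <- function(bank, cutoffHz = 0.09, filterOrder = 4L,
                            labelParity = "even-control") {
  stopifnot(is(bank, "RegressorBank"))
  nFr <- ncol(bank@regressors)
  nyq <- 1 / (2 * bank@paradigm@trS)
  cn <- .parity_sign(nFr, labelParity)
  mod <- t(bank@regressors) * cn              # frames x shifts, on carrier
  filt <- .hp_filtfilt(mod, cutoffHz / nyq, filterOrder) * cn
  out <- t(filt)
  dimnames(out) <- dimnames(bank@regressors)
  out
}
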