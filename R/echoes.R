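#' Voxelwise T2* by log-linear regression
#'
#' Fits the frame-mean signal of each echo to a mono-exponential decay,
#' S(TE) = S0 * exp(-TE / T2*), by ordinary least squares of log mean
#' signal on echo time. Voxels with a non-positive mean at any echo, or a
#' fitted T2* outside `clampMs`, are flagged invalid (no exception is
#' raised). The fit is unweighted, matching the plain log-linear method.
#'
#' @param series a [MultiEchoSeries-class] with at least two echoes
#' @param clampMs admissible T2* range in ms; fits outside it are invalid
#' @return a [T2StarMap-class]
#' @export
fitT2Star <- function(series, clampMs = c(2, 300)) {
  stopifnot(is(series, "MultiEchoSeries"))
  te <- series@teMs
  if (length(te) < 2L) .stopf("at least two echoes are required to fit T2*")
  d <- dim(series@data)
  dims3 <- d[1:3]
  nVox <- prod(dims3)

  # echo x voxel matrix of frame means
  m <- matrix(0, length(te), nVox)
  for (e in seq_along(te))
    m[e, ] <- colMeans(.as_frame_matrix(.echo_array(series, e)))

  valid <- colSums(m > 0) == length(te)
  t2s <- rep(NA_real_, nVox)
  s0 <- rep(NA_real_, nVox)
  if (any(valid)) {
    y <- log(m[, valid, drop = FALSE])
    X <- cbind(1, -te)
    coefs <- solve(crossprod(X), crossprod(X, y))
    t2v <- 1 / coefs[2L, ]
    s0v <- exp(coefs[1L, ])
    ok <- is.finite(t2v) & t2v >= clampMs[1] & t2v <= clampMs[2]
    t2v[!ok] <- NA_real_
    s0v[!ok] <- NA_real_
    t2s[valid] <- t2v
    s0[valid] <- s0v
    valid[valid] <- ok
  }
  new("T2StarMap", t2starMs = array(t2s, dims3), s0 = array(s0, dims3),
      validMask = array(valid, dims3))
}

#' T2*-weighted echo-combination weights
#'
#' Computes per-voxel weights proportional to TE_n * exp(-TE_n / T2*),
#' normalised to sum to one. Voxels without a valid T2* fit receive
#' uniform weights and are flagged in `validMask`.
#'
#' @param t2s a [T2StarMap-class]
#' @param teMs echo times the weights are evaluated at (ms)
#' @return an [EchoWeights-class]
#' @export
computeWeights <- function(t2s, teMs) {
  stopifnot(is(t2s, "T2StarMap"), all(teMs > 0))
  dims3 <- dim(t2s@t2starMs)
  nEch <- length(teMs)
  t2v <- as.vector(t2s@t2starMs)
  w <- vapply(teMs, function(te) te * exp(-te / t2v), numeric(length(t2v)))
  w <- matrix(w, nrow = length(t2v), ncol = nEch)
  tot <- rowSums(w)
  w <- w / tot
  bad <- !as.vector(t2s@validMask) | !is.finite(tot) | tot <= 0
  w[bad, ] <- 1 / nEch
  new("EchoWeights", w = array(w, c(dims3, nEch)), teMs = teMs,
      validMask = array(!bad, dims3))
}

#' Weighted summation of echoes
#'
#' Combines a multi-echo series into a single 4-D series using per-voxel
#' weights held constant over time.
#'
#' @param series a [MultiEchoSeries-class]
#' @param weights an [EchoWeights-class] on the same grid with the same
#'   echo count
#' @return a [VoxelSeries-class]
#' @export
combineEchoes <- function(series, weights) {
  stopifnot(is(series, "MultiEchoSeries"), is(weights, "EchoWeights"))
  d <- dim(series@data)
  if (!identical(dim(weights@w), c(d[1:3], d[5])))
    .stopf("weights grid/echo count (%s) does not match the series (%s)",
           paste(dim(weights@w), collapse = "x"),
           paste(c(d[1:3], d[5]), collapse = "x"))
  out <- array(0, d[1:4])
  for (e in seq_len(d[5])) {
    we <- weights@w[, , , e]
    out <- out + .echo_array(series, e) *
      array(we, d[1:4])  # recycle weights over frames
  }
  new("VoxelSeries", data = out, trS = series@trS,
      labelParity = series@labelParity, voxelSizeMm = series@voxelSizeMm)
}

#' Temporal signal-to-noise ratio
#'
#' tSNR is the frame-mean signal divided by the standard deviation of the
#' noise, with noise defined as the residual between the signal and its
#' best model fit. The residual SD uses the model's residual degrees of
#' freedom when supplied, otherwise frames minus one.
#'
#' @param series a [VoxelSeries-class] or 4-D array
#' @param fitted the model prediction, same shape, or an
#'   [ActivationResult-class] whose `fitted` slot is used (its `dof` then
#'   provides the residual degrees of freedom)
#' @param dof residual degrees of freedom for the residual SD
#' @return 3-D tSNR map; voxels with zero residual variance are `Inf`
#' @export
tsnrMap <- function(series, fitted, dof = NULL) {
  y <- if (is(series, "VoxelSeries")) series@data else series
  if (is(fitted, "ActivationResult")) {
    if (is.null(dof)) dof <- fitted@dof
    fitted <- fitted@fitted
  }
  stopifnot(identical(dim(y), dim(fitted)))
  nFr <- dim(y)[4]
  if (is.null(dof)) dof <- nFr - 1L
  Y <- .as_frame_matrix(y)
  R <- Y - .as_frame_matrix(fitted)
  sdn <- sqrt(colSums(R^2) / dof)
  out <- colMeans(Y) / sdn  # zero residual variance -> Inf, deliberately
  array(out, dim(y)[1:3])
}
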