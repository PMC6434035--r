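#' Gaussian spatial smoothing of a 4-D series
#'
#' Separable Gaussian smoothing per frame with sigma = FWHM / 2.3548 on
#' each axis (in mm, converted by the voxel size). Smoothing is normalised
#' within the mask: the smoothed masked data are divided by the smoothed
#' mask, so a constant volume stays constant inside the mask and no signal
#' bleeds in from outside it.
#'
#' @param series a [VoxelSeries-class] (or 3-D/4-D array with
#'   `voxelSizeMm` given)
#' @param fwhmMm full width at half maximum of the kernel (mm); 0 returns
#'   the input unchanged
#' @param mask logical 3-D array; default all voxels
#' @param voxelSizeMm required when `series` is a bare array
#' @return same type as the input, smoothed
#' @export
smoothSeries <- function(series, fwhmMm = 4.5, mask = NULL,
                         voxelSizeMm = NULL) {
  isS4in <- is(series, "VoxelSeries")
  arr <- if (isS4in) series@data else series
  vs <- if (isS4in) series@voxelSizeMm else voxelSizeMm
  if (is.null(vs)) .stopf("voxelSizeMm is required for array input")
  if (fwhmMm <= 0) return(series)
  d3 <- dim(arr)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d3)
  sigmaVox <- (fwhmMm / 2.3548) / vs
  kerns <- lapply(sigmaVox, function(s) {
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k / sum(k)
  })
  maskN <- .smooth_vol(mask * 1, kerns)
  smoothVol <- function(v) {
    out <- .smooth_vol(v * mask, kerns)
    out[mask] <- out[mask] / maskN[mask]
    out[!mask] <- v[!mask]
    out
  }
  if (length(dim(arr)) == 3L) {
    out <- smoothVol(arr)
  } else {
    out <- arr
    for (f in seq_len(dim(arr)[4])) out[, , , f] <- smoothVol(arr[, , , f])
  }
  if (isS4in) {
    series@data <- out
    series
  } else out
}

# separable 1-D convolutions with zero padding
.smooth_vol <- function(vol, kerns) {
  for (ax in 1:3) vol <- .conv_axis(vol, ax, kerns[[ax]])
  vol
}

.conv_axis <- function(vol, axis, kern) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(vol, perm), nrow = d[axis])
  n <- nrow(m)
  r <- (length(kern) - 1L) / 2L
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kern)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (any(ok)) out[ok, ] <- out[ok, ] + kern[j] * m[src[ok], , drop = FALSE]
  }
  aperm(array(out, d[perm]), order(perm))
}

#' Breath-hold GLM design matrix
#'
#' Columns: intercept, orthogonal polynomial trends up to `trendOrder`,
#' the ASL label/control alternation (if requested), and the breath-hold
#' regressor last. An error names collinear columns if the design is rank
#' deficient.
#'
#' @param regressor breath-hold regressor sampled at the frame grid
#' @param trendOrder polynomial trend order (0 for none)
#' @param alternation logical: include the +/-1 label/control column
#' @param labelParity carrier convention for the alternation column
#' @return design matrix with named columns; the response column is last
#' @export
bhDesign <- function(regressor, trendOrder = 3L, alternation = TRUE,
                     labelParity = "even-control") {
  nFr <- length(regressor)
  X <- matrix(1, nFr, 1L, dimnames = list(NULL, "intercept"))
  if (trendOrder > 0L) {
    P <- stats::poly(seq_len(nFr), degree = trendOrder)
    colnames(P) <- paste0("trend", seq_len(trendOrder))
    X <- cbind(X, P)
  }
  if (alternation)
    X <- cbind(X, labelcontrol = .parity_sign(nFr, labelParity))
  X <- cbind(X, bh = regressor)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    .stopf("design is rank deficient; collinear column(s): %s",
           paste(bad, collapse = ", "))
  }
  X
}

# Vectorised OLS of Y (frames x voxels) on X; statistics for column `coef`.
# r2 is variance explained by that column after projecting out the others.
.fit_glm_matrix <- function(Y, X, coef = ncol(X)) {
  n <- nrow(X)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) .stopf("design is rank deficient")
  coefs <- qr.coef(qrX, Y)
  fitted <- X %*% coefs
  res <- Y - fitted
  ssRes <- colSums(res^2)
  dof <- n - p
  sigma2 <- ssRes / dof
  V <- chol2inv(qr.R(qrX))
  op <- order(qrX$pivot)
  xtxInv <- V[op, op, drop = FALSE]
  se <- sqrt(sigma2 * xtxInv[coef, coef])
  beta <- unname(coefs[coef, ])
  tstat <- unname(beta / se)              # Inf where sigma2 == 0, flagged
  Xn <- X[, -coef, drop = FALSE]
  resN <- Y - Xn %*% qr.coef(qr(Xn), Y)
  ssTotN <- colSums(resN^2)
  r2 <- unname(ifelse(ssTotN > 0, 1 - ssRes / ssTotN, NA_real_))
  list(beta = beta, tstat = tstat, r2 = pmin(pmax(r2, 0), 1),
       intercept = unname(coefs[1L, ]), coefs = coefs, fitted = fitted,
       dof = dof, sigma2 = sigma2)
}

#' Single-regressor breath-hold GLM fit
#'
#' Ordinary least squares of one or more voxel time series on the design
#' returned by [bhDesign()]. Returns the response beta, its t-score
#' (beta / SE), the variance explained by the response after projecting
#' out the nuisance columns, and residual degrees of freedom. With zero
#' residual variance the t-score is infinite (flagged, not an error).
#'
#' @param y numeric vector (one voxel) or frames x voxels matrix
#' @param design design matrix from [bhDesign()]; the response column is
#'   assumed last
#' @return list with `beta`, `tstat`, `r2`, `intercept`, `fitted`, `dof`
#' @export
fitBhGlm <- function(y, design) {
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1L)
  stopifnot(nrow(Y) == nrow(design))
  out <- .fit_glm_matrix(Y, design)
  out[c("beta", "tstat", "r2", "intercept", "fitted", "dof")]
}

#' AR(1) prewhitened GLM fit for one voxel
#'
#' Estimates the AR(1) coefficient of the noise from the regression
#' residuals and refits after applying the whitening transform to both
#' data and design. The lag-one residual autocorrelation is biased toward
#' zero in short scans (the projection onto the design absorbs slow
#' variance), so the estimate is iterated: whiten, re-estimate on the
#' whitened residuals, compose the coefficients, with the standard
#' first-order small-sample correction (1 + 3 rho) / n applied at each
#' step. Coefficients with absolute value at or above 0.99 are clamped
#' with a warning. Whitening with rho = 0 is the identity, so white-noise
#' input reproduces the OLS fit in expectation.
#'
#' @param y voxel time series
#' @param design design matrix; response column last
#' @param iterations estimation iterations (default 2)
#' @return list with `beta`, `tstat`, `r2`, `intercept`, `fitted` (in the
#'   original, unwhitened space), `dof` and `rho`
#' @export
prewhitenAr1 <- function(y, design, iterations = 2L) {
  n <- length(y)
  if (n <= 10L) .stopf("prewhitening needs more than 10 frames")
  W <- function(v, rho) {
    if (rho == 0) return(v)
    c(sqrt(1 - rho^2) * v[1L], v[-1L] - rho * v[-n])
  }
  estRho <- function(yv, Xv) {
    r <- stats::.lm.fit(Xv, yv)$residuals
    d <- sum(r[-1L] * r[-n]) / sum(r^2)
    if (!is.finite(d)) 0 else d + (1 + 3 * d) / n
  }
  rho <- 0
  clamped <- FALSE
  for (it in seq_len(max(1L, iterations))) {
    d <- estRho(W(y, rho), apply(design, 2L, W, rho = rho))
    rho <- (rho + d) / (1 + rho * d)   # compose successive AR(1) factors
    if (abs(rho) >= 0.99) {
      rho <- sign(rho) * 0.99
      clamped <- TRUE
    }
  }
  if (clamped) warning("AR(1) coefficient clamped to +/-0.99")
  yw <- W(y, rho)
  Xw <- apply(design, 2L, W, rho = rho)
  out <- .fit_glm_matrix(matrix(yw, ncol = 1L), Xw)
  list(beta = out$beta, tstat = out$tstat, r2 = out$r2,
       intercept = out$coefs[1L, 1L],
       fitted = as.vector(design %*% out$coefs[, 1L]),
       dof = out$dof, rho = rho)
}

#' Voxelwise hemodynamic-lag sweep
#'
#' Fits the breath-hold GLM independently for every lag-shifted regressor
#' in the bank and, per voxel, keeps the fit whose t-score is the highest
#' positive one. If no shift yields a positive t-score the maximal-t fit
#' is returned with the lag flagged unreliable. Exact ties go to the
#' smaller shift. The reported degrees of freedom are those of the single
#' chosen design, uncorrected for the selection across lags (the max-t
#' selection makes the nominal null anti-conservative; see the vignette).
#'
#' @param series a [VoxelSeries-class] (already detrended or not; the
#'   design carries its own trend columns)
#' @param bank a [RegressorBank-class], or a matrix of regressors
#'   (shifts x frames) with `shiftsS` supplied
#' @param mask logical 3-D analysis mask (default: all voxels)
#' @param trendOrder polynomial trend order in the design
#' @param alternation include the label/control column (TRUE for BOLD
#'   data; FALSE for the PW series)
#' @param prewhiten apply per-voxel AR(1) prewhitening (BOLD only)
#' @param pThreshold one-sided p threshold for the activation mask
#' @param shiftsS shift values when `bank` is a bare matrix
#' @return an [ActivationResult-class]
#' @export
lagSweep <- function(series, bank, mask = NULL, trendOrder = 3L,
                     alternation = TRUE, prewhiten = FALSE,
                     pThreshold = 0.001, shiftsS = NULL) {
  stopifnot(is(series, "VoxelSeries"))
  if (is(bank, "RegressorBank")) {
    regs <- bank@regressors
    shiftsS <- bank@shiftsS
  } else {
    regs <- bank
    if (is.null(shiftsS)) .stopf("shiftsS must accompany a bare regressor matrix")
  }
  nShift <- nrow(regs)
  if (nShift < 1L) .stopf("the regressor bank is empty")
  d <- dim(series@data)
  dims3 <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims3)
  Y <- .as_frame_matrix(series@data)[, as.vector(mask), drop = FALSE]
  nVox <- ncol(Y)

  designs <- lapply(seq_len(nShift), function(i) {
    bhDesign(regs[i, ], trendOrder = trendOrder, alternation = alternation,
             labelParity = series@labelParity)
  })
  p <- ncol(designs[[1L]])
  dof <- nrow(Y) - p

  tMat <- matrix(NA_real_, nShift, nVox)
  bMat <- matrix(NA_real_, nShift, nVox)
  rMat <- matrix(NA_real_, nShift, nVox)
  iMat <- matrix(NA_real_, nShift, nVox)
  fits <- vector("list", nShift)
  for (i in seq_len(nShift)) {
    if (prewhiten) {
      res <- lapply(seq_len(nVox), function(v) prewhitenAr1(Y[, v], designs[[i]]))
      tMat[i, ] <- vapply(res, `[[`, numeric(1), "tstat")
      bMat[i, ] <- vapply(res, `[[`, numeric(1), "beta")
      rMat[i, ] <- vapply(res, `[[`, numeric(1), "r2")
      iMat[i, ] <- vapply(res, `[[`, numeric(1), "intercept")
      fits[[i]] <- vapply(res, `[[`, numeric(nrow(Y)), "fitted")
    } else {
      fit <- .fit_glm_matrix(Y, designs[[i]])
      tMat[i, ] <- fit$tstat
      bMat[i, ] <- fit$beta
      rMat[i, ] <- fit$r2
      iMat[i, ] <- fit$intercept
      fits[[i]] <- fit$fitted
    }
  }

  sel <- integer(nVox)
  reliable <- logical(nVox)
  for (v in seq_len(nVox)) {
    tv <- tMat[, v]
    pos <- which(tv > 0)
    if (length(pos)) {
      sel[v] <- pos[which.max(tv[pos])]   # first max: smallest shift on ties
      reliable[v] <- TRUE
    } else {
      sel[v] <- which.max(tv)
      reliable[v] <- FALSE
    }
  }
  idx <- cbind(sel, seq_len(nVox))
  fittedSel <- matrix(0, nrow(Y), nVox)
  for (i in unique(sel)) {
    cols <- which(sel == i)
    fittedSel[, cols] <- fits[[i]][, cols, drop = FALSE]
  }

  fill <- function(vals) {
    m <- .na_map(dims3)
    m[mask] <- vals
    m
  }
  tcrit <- stats::qt(1 - pThreshold, dof)
  tSel <- tMat[idx]
  active <- array(FALSE, dims3)
  active[mask] <- tSel > tcrit
  rel <- array(NA, dims3)
  rel[mask] <- reliable

  fitted4 <- array(0, d)
  full <- matrix(0, nrow(Y), prod(dims3))
  full[, as.vector(mask)] <- fittedSel
  fitted4 <- .as_series_array(full, dims3)

  new("ActivationResult", beta = fill(bMat[idx]), tstat = fill(tSel),
      lagS = fill(shiftsS[sel]), r2 = fill(rMat[idx]),
      intercept = fill(iMat[idx]), dof = dof, fitted = fitted4,
      reliableLag = rel, activeMask = active, pThreshold = pThreshold,
      mask = mask)
}

#' Threshold an activation map
#'
#' One-sided Student threshold at the result's degrees of freedom:
#' voxels with t above `qt(1 - p, dof)` are active.
#'
#' @param result an [ActivationResult-class]
#' @param p one-sided uncorrected p threshold
#' @return logical 3-D mask
#' @export
thresholdActivation <- function(result, p = 0.001) {
  stopifnot(is(result, "ActivationResult"), result@dof > 0)
  tcrit <- stats::qt(1 - p, result@dof)
  out <- array(FALSE, dim(result@tstat))
  out[result@mask] <- result@tstat[result@mask] > tcrit
  out
}

#' Fraction of active voxels within a mask
#'
#' @param activeMask logical 3-D activation mask
#' @param gmMask logical 3-D tissue mask (must be nonempty)
#' @return fraction of `gmMask` voxels that are active
#' @export
fractionActive <- function(activeMask, gmMask) {
  if (!any(gmMask)) .stopf("the tissue mask is empty")
  sum(activeMask & gmMask) / sum(gmMask)
}
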