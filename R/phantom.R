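#' Ground truth for the default digital phantom
#'
#' Builds a small 3-D grid with a white-matter core and a gray-matter ring
#' (concentric cylinders through the slice direction) and plausible 3-T
#' tissue values: GM T2* 50 ms, WM T2* 45 ms, GM fractional BOLD change
#' 1.7 percent at TE = 25 ms with WM at half that, GM CBF ratio 1.5 during
#' breath-hold (WM 1.25), and a 1 percent (of S0) perfusion alternation
#' amplitude in GM (0.4 percent in WM). Response lags cycle over the full
#' regressor-bank shift range across brain voxels (in array index order)
#' so every lag is represented in both tissues.
#'
#' @param dims grid size (x, y, z)
#' @param voxelSizeMm voxel edge lengths (mm)
#' @param trS repetition time used to express lags (s)
#' @param s0 baseline zero-TE signal (arbitrary units)
#' @param t2sGmMs,t2sWmMs baseline T2* in GM and WM (ms)
#' @param cvrGm fractional BOLD change at `referenceTeMs` in GM; WM gets
#'   half this value
#' @param cbfRatioGm,cbfRatioWm CBF / CBF0 at the response peak
#' @param perfFracGm,perfFracWm label/control alternation amplitude as a
#'   fraction of S0
#' @param referenceTeMs TE at which `cvrGm` is defined (ms)
#' @param noiseSd additive Gaussian noise standard deviation (signal
#'   units); the default gives a gray-matter temporal SNR of about 100 at
#'   the reference TE, the regime reported for in-vivo multi-echo BOLD.
#'   Use 0 for a noiseless phantom.
#' @param arCoef AR(1) coefficient of the noise
#' @param lagSetS lags to cycle over (s); defaults to the full bank range
#' @param seed RNG seed stored with the truth
#' @return a [PhantomTruth-class]
#' @export
phantomTruth <- function(dims = c(12L, 12L, 8L), voxelSizeMm = c(3, 3, 3),
                         trS = 4, s0 = 1000, t2sGmMs = 50, t2sWmMs = 45,
                         cvrGm = 0.017, cbfRatioGm = 1.5, cbfRatioWm = 1.25,
                         perfFracGm = 0.01, perfFracWm = 0.004,
                         referenceTeMs = 25,
                         noiseSd = s0 * exp(-referenceTeMs / t2sGmMs) / 100,
                         arCoef = 0,
                         lagSetS = defaultShifts(trS), seed = 1L) {
  dims <- as.integer(dims)
  cx <- (dims[1] + 1) / 2
  cy <- (dims[2] + 1) / 2
  r <- sqrt(outer((seq_len(dims[1]) - cx)^2, (seq_len(dims[2]) - cy)^2, "+"))
  rWm <- min(dims[1:2]) / 4.5
  rGm <- min(dims[1:2]) / 2.2
  wm2d <- r <= rWm
  gm2d <- r > rWm & r <= rGm
  gm <- array(rep(gm2d, dims[3]), dims)
  wm <- array(rep(wm2d, dims[3]), dims)
  brain <- gm | wm

  fill <- function(gmVal, wmVal) {
    m <- array(0, dims)
    m[gm] <- gmVal
    m[wm] <- wmVal
    m
  }
  s0Map <- fill(s0, s0)
  t2s <- fill(t2sGmMs, t2sWmMs)
  t2s[!brain] <- t2sGmMs  # harmless filler outside the brain
  cvr <- fill(cvrGm, cvrGm / 2)
  cbf <- fill(cbfRatioGm, cbfRatioWm)
  cbf[!brain] <- 1
  perf <- fill(perfFracGm * s0, perfFracWm * s0)

  # deterministic lag assignment: cycle the lag set over brain voxels in
  # index order, so every shift in the bank is represented
  lag <- array(0, dims)
  lag[brain] <- lagSetS[(seq_len(sum(brain)) - 1L) %% length(lagSetS) + 1L]

  new("PhantomTruth", gmMask = gm, wmMask = wm, s0Map = s0Map,
      t2starMs = t2s, lagS = lag, cvr = cvr, cbfRatio = cbf,
      perfusionAmp = perf, referenceTeMs = referenceTeMs,
      noiseSd = noiseSd, arCoef = arCoef, voxelSizeMm = voxelSizeMm,
      seed = as.integer(seed))
}

#' Generate a synthetic multi-echo ASL/BOLD acquisition
#'
#' Simulates, for every voxel, frame n and echo e:
#' \deqn{S(e, n) = S_0(n) \exp(-TE_e R_2^*(n)) + \epsilon}
#' where the transverse relaxation rate is modulated by the lag-shifted
#' breath-hold response x(n) so that the fractional signal change at the
#' reference TE equals the voxel's true CVR,
#' \eqn{R_2^*(n) = 1/T_2^* - \log(1 + CVR \cdot x(n)) / TE_{ref}},
#' and the zero-TE signal carries the ASL label/control alternation
#' \eqn{S_0(n) = S_0 (1 + a/S_0 \cdot c(n) (1 + (CBF_{ratio}-1) x(n)))}
#' with c(n) = +1 on control frames and -1 on label frames. Noise is
#' i.i.d. Gaussian per echo and frame (optionally AR(1) along time).
#' Output is bit-identical for a fixed `truth@seed`.
#'
#' @param truth a [PhantomTruth-class]
#' @param paradigm a [Paradigm-class]; its TR and frame grid are used
#' @param teMs echo times (ms)
#' @param hrfParams HRF parameters forwarded to [buildRegressorBank()]
#' @return a [MultiEchoSeries-class]
#' @export
generatePhantom <- function(truth, paradigm = buildParadigm(),
                            teMs = c(9.1, 25, 39.6, 54.3),
                            hrfParams = list()) {
  stopifnot(is(truth, "PhantomTruth"), is(paradigm, "Paradigm"))
  dims <- dim(truth@gmMask)
  nFr <- nFrames(paradigm)
  if (nFr < 2L) .stopf("paradigm must provide at least 2 functional frames")
  nEch <- length(teMs)

  lags <- sort(unique(as.vector(truth@lagS)))
  bank <- buildRegressorBank(paradigm, shiftsS = lags, hrfParams = hrfParams)
  lagRow <- match(as.vector(truth@lagS), bank@shiftsS)

  nVox <- prod(dims)
  # frames x voxels response, per-voxel lag
  x <- t(bank@regressors[lagRow, , drop = FALSE])

  s0 <- as.vector(truth@s0Map)
  cvr <- as.vector(truth@cvr)
  aFrac <- ifelse(s0 > 0, as.vector(truth@perfusionAmp) / s0, 0)
  dR <- as.vector(truth@cbfRatio) - 1
  r2s0 <- 1 / as.vector(truth@t2starMs)
  cn <- .parity_sign(nFr, "even-control")

  # frames x voxels modulations
  logTerm <- log1p(sweep(x, 2L, cvr, "*")) / truth@referenceTeMs
  perf <- (1 + sweep(x, 2L, dR, "*")) * cn
  s0n <- sweep(1 + sweep(perf, 2L, aFrac, "*"), 2L, s0, "*")

  data <- array(0, c(dims, nFr, nEch))
  noise <- if (truth@noiseSd > 0) {
    .with_seed(truth@seed, {
      eps <- array(stats::rnorm(nVox * nFr * nEch, sd = truth@noiseSd),
                   c(nFr, nVox, nEch))
      if (truth@arCoef != 0) {
        rho <- truth@arCoef
        eps[1L, , ] <- eps[1L, , ] / sqrt(1 - rho^2)
        for (n in 2:nFr) eps[n, , ] <- rho * eps[n - 1L, , ] + eps[n, , ]
        eps <- eps * sqrt(1 - rho^2)  # stationary sd back to noiseSd
      }
      eps
    })
  } else NULL

  for (e in seq_len(nEch)) {
    sig <- s0n * exp(-teMs[e] * sweep(-logTerm, 2L, r2s0, "+"))
    if (!is.null(noise)) sig <- sig + noise[, , e]
    if (any(sig[, s0 > 0] < 0))
      .stopf("negative signal generated at TE %g ms; lower the modulation or noiseSd",
             teMs[e])
    data[, , , , e] <- .as_series_array(sig, dims)
  }
  new("MultiEchoSeries", data = data, teMs = teMs, trS = paradigm@trS,
      labelParity = "even-control", voxelSizeMm = truth@voxelSizeMm)
}

#' Perturb a phantom truth for a second session
#'
#' Returns the truth with optional voxelwise multiplicative jitter on the
#' CVR and CBF-ratio maps (emulating between-visit physiological
#' variability), restricted to the given mask, plus a fresh seed so the
#' noise realisation differs.
#'
#' @param truth a [PhantomTruth-class]
#' @param cvrJitter,cbfJitter standard deviation of the multiplicative
#'   jitter (e.g. 0.1 for 10 percent); 0 leaves the map unchanged
#' @param mask logical array restricting the perturbation (default: whole
#'   grid)
#' @param seed seed for the jitter draw and the new session's noise
#' @return a perturbed [PhantomTruth-class]
#' @export
secondSession <- function(truth, cvrJitter = 0, cbfJitter = 0, mask = NULL,
                          seed = truth@seed + 1L) {
  stopifnot(cvrJitter >= 0, cbfJitter >= 0)
  dims <- dim(truth@gmMask)
  if (is.null(mask)) mask <- array(TRUE, dims)
  out <- truth
  .with_seed(seed, {
    if (cvrJitter > 0) {
      f <- 1 + cvrJitter * stats::rnorm(sum(mask))
      out@cvr[mask] <- truth@cvr[mask] * pmax(f, 0.05)
    }
    if (cbfJitter > 0) {
      g <- 1 + cbfJitter * stats::rnorm(sum(mask))
      rr <- 1 + (truth@cbfRatio[mask] - 1) * pmax(g, 0.05)
      out@cbfRatio[mask] <- pmax(rr, 0.05)
    }
  })
  out@seed <- as.integer(seed)
  out
}
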