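#' Construct a breath-hold paradigm
#'
#' Builds and validates the timing of a breath-hold acquisition. The default
#' arguments encode a 356-s protocol: 64 s of calibration frames, a 44-s
#' paced lead-in, four cycles of 16-s breath-hold on expiration, 16-s
#' self-paced recovery and 24-s paced breathing, and a final 24-s paced
#' tail, at TR = 4 s, giving 73 functional frames.
#'
#' @param leadInS paced-breathing lead-in (s)
#' @param nCycles number of breath-hold cycles
#' @param bhS breath-hold duration per cycle (s)
#' @param recoveryS recovery duration per cycle (s)
#' @param pacedS paced-breathing duration per cycle (s)
#' @param tailS final paced-breathing duration (s)
#' @param calibrationS discarded calibration period (s)
#' @param trS repetition time (s)
#' @return a validated [Paradigm-class]
#' @examples
#' p <- buildParadigm()
#' totalDuration(p)  # 356
#' nFrames(p)        # 73
#' @export
buildParadigm <- function(leadInS = 44, nCycles = 4, bhS = 16, recoveryS = 16,
                          pacedS = 24, tailS = 24, calibrationS = 64,
                          trS = 4) {
  new("Paradigm", leadInS = leadInS, nCycles = as.integer(nCycles), bhS = bhS,
      recoveryS = recoveryS, pacedS = pacedS, tailS = tailS,
      calibrationS = calibrationS, trS = trS)
}

#' Breath-hold indicator sampled on a fine grid
#'
#' Returns the task square wave on the functional timeline (calibration
#' excluded): 1 during breath-hold intervals, 0 elsewhere, sampled every
#' `dt` seconds starting at time 0 (the first retained frame).
#'
#' @param paradigm a [Paradigm-class]
#' @param dt sampling step (s); must divide every block duration
#' @return numeric vector of length `functionalDuration(paradigm) / dt`
#' @export
boxcar <- function(paradigm, dt = 0.1) {
  stopifnot(is(paradigm, "Paradigm"), dt > 0)
  durs <- c(paradigm@leadInS, paradigm@bhS, paradigm@recoveryS,
            paradigm@pacedS, paradigm@tailS)
  if (any(abs(durs / dt - round(durs / dt)) > 1e-8))
    .stopf("dt = %g s does not divide all block durations (%s s)", dt,
           paste(durs, collapse = ", "))
  nf <- round(functionalDuration(paradigm) / dt)
  t <- (seq_len(nf) - 1L) * dt
  ind <- numeric(nf)
  cyc <- paradigm@bhS + paradigm@recoveryS + paradigm@pacedS
  for (i in seq_len(paradigm@nCycles)) {
    start <- paradigm@leadInS + (i - 1L) * cyc
    ind[t >= start - 1e-9 & t < start + paradigm@bhS - 1e-9] <- 1
  }
  ind
}

#' Double-gamma hemodynamic response function
#'
#' Canonical two-gamma HRF: a positive response gamma density minus a
#' scaled undershoot gamma density, normalised to unit peak. With the
#' default parameters the kernel peaks close to 5 s and has a late
#' undershoot.
#'
#' @param dt sampling step (s)
#' @param peakDelayS,undershootDelayS shape x dispersion products of the
#'   two gamma components (s)
#' @param peakDispS,undershootDispS dispersions of the two components (s)
#' @param undershootRatio amplitude of the undershoot relative to the peak
#'   component
#' @param durationS kernel support (s)
#' @return numeric kernel sampled at `seq(0, durationS, by = dt)`, unit peak
#' @export
doubleGammaHrf <- function(dt = 0.1, peakDelayS = 6, undershootDelayS = 16,
                           peakDispS = 1, undershootDispS = 1,
                           undershootRatio = 1 / 6, durationS = 32) {
  stopifnot(dt > 0)
  t <- seq(0, durationS, by = dt)
  h <- stats::dgamma(t, shape = peakDelayS / peakDispS, scale = peakDispS) -
    undershootRatio *
      stats::dgamma(t, shape = undershootDelayS / undershootDispS,
                    scale = undershootDispS)
  h / max(h)
}

#' Default lag shifts for the breath-hold regressor bank
#'
#' Multiples of the TR from -2 TR to +8 TR inclusive (11 shifts).
#'
#' @param trS repetition time (s)
#' @return numeric vector of shifts (s)
#' @export
defaultShifts <- function(trS = 4) seq(-2L, 8L) * trS

#' Build the lag-shifted breath-hold regressor bank
#'
#' Convolves the breath-hold square wave with the double-gamma HRF on a
#' fine time grid, normalises the response to unit peak, then shifts it by
#' each entry of `shiftsS` (zero-padding at the edges; support sliding past
#' the scan is truncated, not wrapped) and samples it at the functional
#' frame times `0, TR, 2 TR, ...`.
#'
#' @param paradigm a [Paradigm-class]
#' @param shiftsS time shifts in seconds; must be multiples of the TR
#'   within `[-2 TR, 8 TR]`
#' @param fineDt fine-grid step for the convolution (s)
#' @param hrfParams named list passed to [doubleGammaHrf()]
#' @return a [RegressorBank-class] with one row per shift
#' @export
buildRegressorBank <- function(paradigm, shiftsS = defaultShifts(paradigm@trS),
                               fineDt = 0.1, hrfParams = list()) {
  stopifnot(is(paradigm, "Paradigm"))
  tr <- paradigm@trS
  mult <- shiftsS / tr
  if (any(abs(mult - round(mult)) > 1e-8))
    .stopf("shifts must be multiples of the TR (%g s)", tr)
  if (any(shiftsS < -2 * tr - 1e-9) || any(shiftsS > 8 * tr + 1e-9))
    .stopf("shifts must lie within [-2 TR, 8 TR] = [%g, %g] s", -2 * tr, 8 * tr)
  shiftsS <- sort(shiftsS)

  fine <- convolvedResponse(paradigm, fineDt = fineDt, hrfParams = hrfParams)
  nFine <- length(fine)
  nFr <- nFrames(paradigm)
  frameIdx <- round((seq_len(nFr) - 1L) * tr / fineDt) + 1L

  reg <- matrix(0, nrow = length(shiftsS), ncol = nFr)
  for (i in seq_along(shiftsS)) {
    off <- round(shiftsS[i] / fineDt)
    shifted <- numeric(nFine)
    src <- seq_len(nFine) - off
    ok <- src >= 1L & src <= nFine
    shifted[ok] <- fine[src[ok]]
    if (all(shifted == 0) && any(fine != 0))
      .stopf("shift %g s pushes the response support outside the scan",
             shiftsS[i])
    reg[i, ] <- shifted[frameIdx]
  }
  dimnames(reg) <- list(sprintf("shift%+g", shiftsS), NULL)
  new("RegressorBank", shiftsS = shiftsS, regressors = reg,
      hrfParams = hrfParams, fineDt = fineDt, paradigm = paradigm)
}

#' Unshifted HRF-convolved breath-hold response on the fine grid
#'
#' @inheritParams buildRegressorBank
#' @return numeric vector, unit peak (all-zero for a cycle-free paradigm)
#' @export
convolvedResponse <- function(paradigm, fineDt = 0.1, hrfParams = list()) {
  box <- boxcar(paradigm, dt = fineDt)
  hrf <- do.call(doubleGammaHrf, c(list(dt = fineDt), hrfParams))
  conv <- stats::convolve(c(box, numeric(length(hrf))), rev(hrf),
                          type = "open")[seq_along(box)] * fineDt
  if (max(conv) > 0) conv <- conv / max(conv)
  conv
}

#' Write a regressor bank as a delimited text matrix
#'
#' Frames in rows, one column per shift, tab-delimited with a header.
#'
#' @param bank a [RegressorBank-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeRegressorBank <- function(bank, path) {
  m <- t(bank@regressors)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = colnames(m))
  invisible(path)
}
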