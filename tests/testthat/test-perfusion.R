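mkSeries <- function(Y, labelParity = "even-control") {
  # Y: frames x voxels -> 1 x voxels x 1 grid
  nVox <- ncol(Y)
  data <- array(t(Y), c(nVox, 1L, 1L, nrow(Y)))
  new("VoxelSeries", data = aperm(data, c(2, 1, 3, 4)),
      trS = 4, labelParity = labelParity, voxelSizeMm = c(3, 3, 3))
}

test_that("label/control regression removes the alternation span exactly", {
  n <- 73L
  cn <- rep_len(c(1, -1), n)
  Y <- cbind(50 + 3 * cn,                    # pure alternation + offset
             sin(seq_len(n) / 9))            # already orthogonal-ish
  s <- mkSeries(Y)
  out <- regressLabelControl(s)
  y1 <- out@data[1, 1, 1, ]
  expect_equal(y1, rep(50, n), tolerance = 1e-10)
  # projection idempotence
  out2 <- regressLabelControl(out)
  expect_equal(out2@data, out@data, tolerance = 1e-10)
  # output orthogonal to the demeaned alternation
  cd <- cn - mean(cn)
  expect_lt(abs(sum(out@data[1, 2, 1, ] * cd)), 1e-8)
  expect_error(regressLabelControl(mkSeries(Y[1:3, , drop = FALSE])),
               "at least 4 frames")
})

test_that("alternation regression suppresses near-Nyquist power on the phantom", {
  ph <- noiselessPhantom()
  e2 <- asVoxelSeries(ph$series, 2L)
  cleaned <- regressLabelControl(e2)
  v <- which(ph$truth@gmMask, arr.ind = TRUE)[5, ]
  topPower <- function(y) {
    n <- length(y)
    P <- abs(stats::fft(y - mean(y)))^2
    f <- (seq_len(n) - 1) / n
    sum(P[f > 0.45 & f <= 0.5])
  }
  before <- topPower(e2@data[v[1], v[2], v[3], ])
  after <- topPower(cleaned@data[v[1], v[2], v[3], ])
  expect_lt(after / before, 0.01)
})

test_that("polynomial detrending removes trends and keeps the mean", {
  n <- 73L
  t <- seq_len(n)
  cubic <- 5 + 0.2 * t - 0.01 * t^2 + 1e-4 * t^3
  s <- mkSeries(cbind(cubic))
  out <- detrendPoly(s, 3L)
  y <- out@data[1, 1, 1, ]
  expect_equal(y, rep(mean(cubic), n), tolerance = 1e-8)
  # order 0 leaves a constant series unchanged
  cs <- mkSeries(cbind(rep(4, n)))
  expect_equal(detrendPoly(cs, 0L)@data, cs@data)
  # idempotence
  s2 <- mkSeries(cbind(cubic + sin(t)))
  once <- detrendPoly(s2, 3L)
  expect_equal(detrendPoly(once, 3L)@data, once@data, tolerance = 1e-10)
  expect_error(detrendPoly(mkSeries(cbind(1:4)), 3L), "frames")
})

test_that("PW extraction demodulates a pure alternation", {
  n <- 72L
  cn <- rep_len(c(1, -1), n)
  d <- 3
  s <- mkSeries(cbind(100 + d * cn, rep(100, n)))
  pw <- pwFromEcho1(s)
  expect_s4_class(pw, "PwSeries")
  y <- pw@data[1, 1, 1, ]
  expect_equal(mean(y), d, tolerance = 0.02 * d)
  # no alternation -> output negligible against the carrier amplitude
  expect_lt(max(abs(pw@data[1, 2, 1, ])), 0.01 * d)
})

test_that("PW is antisymmetric under label/control swap", {
  ph <- noiselessPhantom()
  pw1 <- pwFromEcho1(ph$series)
  swapped <- ph$series
  swapped@labelParity <- "odd-control"
  pw2 <- pwFromEcho1(swapped)
  expect_equal(pw1@data, -pw2@data)
})

test_that("demodulation is an involution on the high-passed series", {
  ph <- noiselessPhantom()
  pw <- pwFromEcho1(ph$series)
  n <- dim(pw@data)[4]
  cn <- rep_len(c(1, -1), n)
  hp <- sweep(pw@data, 4, cn, "*")       # undo the demodulation
  redemod <- sweep(hp, 4, cn, "*")       # apply it twice
  expect_equal(redemod, pw@data)
})

test_that("PW baseline recovers the phantom perfusion amplitude", {
  ph <- noiselessPhantom()
  truth <- ph$truth
  pw <- pwFromEcho1(ph$series)
  base <- apply(pw@data, 1:3, mean)
  gm <- truth@gmMask
  ampTe1 <- truth@perfusionAmp * exp(-ph$series@teMs[1] / truth@t2starMs)
  relErr <- abs(base[gm] / ampTe1[gm] - 1)
  expect_lt(max(relErr), 0.10)
})

test_that("cutoff at or above Nyquist is rejected", {
  ph <- noiselessPhantom()
  expect_error(pwFromEcho1(ph$series, cutoffHz = 0.125), "Nyquist")
})

test_that("filtered PW regressors match the data operator", {
  p <- protocolParadigm()
  bank <- buildRegressorBank(p)
  pwReg <- pwRegressorBank(bank)
  expect_equal(dim(pwReg), dim(bank@regressors))
  # pushing a regressor-shaped modulated signal through pwFromEcho1 must
  # give the same transform
  i0 <- which(shifts(bank) == 0)
  x <- bank@regressors[i0, ]
  cn <- rep_len(c(1, -1), length(x))
  s <- mkSeries(cbind(x * cn))
  viaData <- pwFromEcho1(s)@data[1, 1, 1, ]
  expect_equal(viaData, unname(pwReg[i0, ]), tolerance = 1e-10)
})
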