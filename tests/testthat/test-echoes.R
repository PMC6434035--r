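test_that("log-linear fit recovers a noiseless exponential exactly", {
  me <- syntheticExpSeries(s0 = 1000, t2star = 30)
  fit <- fitT2Star(me)
  expect_true(all(fit@validMask))
  expect_equal(as.vector(fit@t2starMs), rep(30, length(fit@t2starMs)),
               tolerance = 1e-10)
  expect_equal(as.vector(fit@s0), rep(1000, length(fit@s0)),
               tolerance = 1e-9)
})

test_that("two-echo fit equals the closed-form solution", {
  te <- c(12, 40)
  m1 <- 800
  m2 <- 310
  me <- syntheticExpSeries(teMs = te, dims = c(1L, 1L, 1L))
  me@data[, , , , 1] <- m1
  me@data[, , , , 2] <- m2
  fit <- fitT2Star(me)
  expect_equal(fit@t2starMs[1, 1, 1], (te[2] - te[1]) / log(m1 / m2),
               tolerance = 1e-12)
})

test_that("voxels with non-positive means are flagged, not fatal", {
  me <- syntheticExpSeries()
  me@data[1, 1, 1, , ] <- 0
  me@data[2, 1, 1, , 2] <- -me@data[2, 1, 1, , 2]
  fit <- fitT2Star(me)
  expect_false(fit@validMask[1, 1, 1])
  expect_false(fit@validMask[2, 1, 1])
  expect_true(is.na(fit@t2starMs[1, 1, 1]))
  # invalid voxels get uniform fallback weights, flagged
  w <- computeWeights(fit, me@teMs)
  expect_false(w@validMask[1, 1, 1])
  expect_equal(w@w[1, 1, 1, ], rep(0.25, 4))
})

test_that("flat decay outside the T2* clamp is invalidated", {
  me <- syntheticExpSeries(t2star = 1e6)
  fit <- fitT2Star(me)
  expect_false(any(fit@validMask))
})

test_that("echo weights are normalised and match the formula limits", {
  te <- c(9.1, 25, 39.6, 54.3)
  mkMap <- function(t2) {
    dims <- c(2L, 2L, 1L)
    new("T2StarMap", t2starMs = array(t2, dims), s0 = array(1000, dims),
        validMask = array(TRUE, dims))
  }
  # generic normalisation
  w <- computeWeights(mkMap(42), te)
  expect_equal(apply(w@w, 1:3, sum), array(1, c(2, 2, 1)))
  expect_true(all(w@w >= 0))
  # T2* -> infinity limit: weights proportional to TE
  wInf <- computeWeights(mkMap(1e12), te)
  expect_equal(wInf@w[1, 1, 1, ], te / sum(te), tolerance = 1e-9)
  expect_equal(te / sum(te), c(0.0711, 0.1953, 0.3094, 0.4242),
               tolerance = 5e-4)
  # TE * exp(-TE / T2*) is maximal at TE = T2* among available echoes
  w25 <- computeWeights(mkMap(25), te)
  expect_equal(which.max(w25@w[1, 1, 1, ]), 2L)
  # single echo gets weight one
  w1 <- computeWeights(mkMap(50), 25)
  expect_equal(as.vector(w1@w), rep(1, 4))
})

test_that("combination is an exact weighted sum and is linear", {
  ph <- noiselessPhantom()
  me <- ph$series
  dims <- dim(me@data)[1:3]
  pick <- function(v) {
    w <- array(0, c(dims, 4))
    for (e in 1:4) w[, , , e] <- v[e]
    new("EchoWeights", w = w, teMs = me@teMs,
        validMask = array(TRUE, dims))
  }
  # weight on echo 1 only reproduces echo 1
  c1 <- combineEchoes(me, pick(c(1, 0, 0, 0)))
  expect_equal(c1@data, me@data[, , , , 1])
  # uniform weights on identical echoes reproduce the series
  meSame <- me
  for (e in 2:4) meSame@data[, , , , e] <- meSame@data[, , , , 1]
  cu <- combineEchoes(meSame, pick(rep(0.25, 4)))
  expect_equal(cu@data, meSame@data[, , , , 1], tolerance = 1e-12)
  # linearity in the input for fixed weights
  w <- computeWeights(fitT2Star(me), me@teMs)
  meB <- me
  meB@data <- me@data[ , , , , , drop = FALSE] * 0.5 + 7
  lhs <- combineEchoes(meB, w)@data
  rhs <- 0.5 * combineEchoes(me, w)@data + 7
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # shape mismatch is an error
  badW <- pick(c(1, 0, 0, 0))
  badW@w <- badW@w[, , , 1:3, drop = FALSE]
  expect_error(combineEchoes(me, badW), "does not match")
})

test_that("noisy T2* fit agrees with a nonlinear oracle in GM", {
  truth <- phantomTruth(cvrGm = 0, perfFracGm = 0, perfFracWm = 0,
                        cbfRatioGm = 1, cbfRatioWm = 1, seed = 5L)
  me <- generatePhantom(truth, protocolParadigm())
  fit <- fitT2Star(me)
  gm <- truth@gmMask & fit@validMask
  relErr <- abs(fit@t2starMs[gm] / truth@t2starMs[gm] - 1)
  expect_lt(median(relErr), 0.05)

  # cross-check a handful of voxels against nonlinear least squares
  idx <- which(gm, arr.ind = TRUE)[1:10, , drop = FALSE]
  for (i in seq_len(nrow(idx))) {
    v <- idx[i, ]
    means <- vapply(1:4, function(e) mean(me@data[v[1], v[2], v[3], , e]),
                    numeric(1))
    nl <- stats::nls(means ~ s0 * exp(-te / t2), data = list(te = me@teMs),
                     start = list(s0 = fit@s0[v[1], v[2], v[3]],
                                  t2 = fit@t2starMs[v[1], v[2], v[3]]))
    expect_equal(fit@t2starMs[v[1], v[2], v[3]], coef(nl)[["t2"]],
                 tolerance = 0.02)
  }
})

test_that("tSNR is mean over residual noise and scales as expected", {
  set.seed(31)
  dims <- c(8L, 8L, 4L)
  nFr <- 73L
  fittedArr <- array(100, c(dims, nFr))
  noise <- array(rnorm(prod(dims) * nFr, sd = 5), c(dims, nFr))
  noise <- noise - array(apply(noise, 1:3, mean), c(dims, nFr))
  series <- fittedArr + noise
  m <- tsnrMap(series, fittedArr, dof = nFr - 1L)
  expect_equal(median(m), 100 / 5, tolerance = 0.05)
  # doubling the noise halves tSNR exactly for the same realisation
  m2 <- tsnrMap(fittedArr + 2 * noise, fittedArr, dof = nFr - 1L)
  expect_equal(as.vector(m2), as.vector(m) / 2, tolerance = 1e-12)
  # perfect fit is flagged infinite
  mInf <- tsnrMap(fittedArr, fittedArr)
  expect_true(all(is.infinite(mInf)))
})
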