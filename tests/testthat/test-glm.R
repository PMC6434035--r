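test_that("Gaussian smoothing has the requested FWHM and conserves constants", {
  dims <- c(21L, 21L, 21L)
  vox <- c(1, 1, 1)
  imp <- array(0, dims)
  imp[11, 11, 11] <- 1
  fwhm <- 4.5
  sm <- smoothSeries(imp, fwhm, voxelSizeMm = vox)
  prof <- sm[, 11, 11]
  half <- max(prof) / 2
  # half-max crossings by linear interpolation
  cross <- function(p) {
    above <- which(p >= half)
    lo <- min(above)
    hi <- max(above)
    xl <- lo - 1 + (half - p[lo - 1]) / (p[lo] - p[lo - 1])
    xr <- hi + (p[hi] - half) / (p[hi] - p[hi + 1])
    xr - xl
  }
  expect_equal(cross(prof), fwhm, tolerance = 0.05)

  mask <- array(TRUE, dims)
  mask[1:5, , ] <- FALSE
  const <- array(3, dims)
  smc <- smoothSeries(const, fwhm, mask = mask, voxelSizeMm = vox)
  expect_equal(smc[mask], rep(3, sum(mask)), tolerance = 1e-12)

  set.seed(2)
  noisy <- array(rnorm(prod(dims)), dims)
  smn <- smoothSeries(noisy, fwhm, voxelSizeMm = vox)
  expect_lt(stats::var(as.vector(smn)), stats::var(as.vector(noisy)))
})

test_that("design construction flags collinearity by column name", {
  bank <- buildRegressorBank(protocolParadigm())
  X <- bhDesign(bank@regressors[3, ])
  expect_equal(colnames(X),
               c("intercept", "trend1", "trend2", "trend3", "labelcontrol", "bh"))
  expect_error(bhDesign(rep(1, 73)), "bh")
})

test_that("single-voxel GLM recovers exact and orthogonal cases", {
  bank <- buildRegressorBank(protocolParadigm())
  x <- bank@regressors[which(shifts(bank) == 0), ]
  X <- bhDesign(x)
  n <- length(x)
  # exact model: infinite t, full variance explained
  fit <- fitBhGlm(100 + 5 * x, X)
  expect_equal(fit$beta, 5, tolerance = 1e-9)
  expect_true(is.infinite(fit$tstat) | fit$tstat > 1e6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  # orthogonal input: beta ~ 0
  cn <- rep_len(c(1, -1), n)
  fit0 <- fitBhGlm(cn * 2 + 7, X)
  expect_equal(fit0$beta, 0, tolerance = 1e-9)
})

test_that("GLM standard errors match the analytic covariance", {
  set.seed(77)
  bank <- buildRegressorBank(protocolParadigm())
  X <- bhDesign(bank@regressors[3, ])
  n <- nrow(X)
  betaTrue <- 2
  nrep <- 1000L
  Y <- outer(X[, "bh"], rep(betaTrue, nrep)) + matrix(rnorm(n * nrep), n)
  fit <- fitBhGlm(Y, X)
  seAnalytic <- sqrt(solve(crossprod(X))["bh", "bh"])
  expect_equal(mean(fit$beta), betaTrue, tolerance = 4 * seAnalytic / sqrt(nrep))
  expect_equal(stats::sd(fit$beta), seAnalytic, tolerance = 0.1 * seAnalytic)
})

test_that("lag sweep picks the constructed shift and breaks ties low", {
  p <- protocolParadigm()
  bank <- buildRegressorBank(p)
  iTrue <- which(shifts(bank) == 12)        # 3 TR
  n <- ncol(bank@regressors)
  mk <- function(y) new("VoxelSeries", data = array(y, c(1, 1, 1, n)),
                        trS = 4, labelParity = "even-control",
                        voxelSizeMm = c(3, 3, 3))
  res <- lagSweep(mk(200 + 10 * bank@regressors[iTrue, ]), bank)
  expect_equal(res@lagS[1, 1, 1], 12)
  expect_true(res@reliableLag[1, 1, 1])
  expect_equal(res@r2[1, 1, 1], 1, tolerance = 1e-9)

  # duplicated regressor rows tie exactly: the smaller shift wins
  dup <- bank@regressors[c(iTrue, iTrue), ]
  set.seed(8)
  y <- 200 + 10 * bank@regressors[iTrue, ] + rnorm(n)
  resTie <- lagSweep(mk(y), dup, shiftsS = c(4, 20))
  expect_equal(resTie@lagS[1, 1, 1], 4)

  # max over the bank cannot fall below any single-shift fit
  single <- fitBhGlm(y, bhDesign(bank@regressors[1, ]))
  expect_gte(resTie@tstat[1, 1, 1], single$tstat)

  # a voxel anticorrelated with every offered regressor has no positive
  # t-score: the maximal-t fit is kept but the lag is flagged unreliable
  adj <- bank@regressors[shifts(bank) %in% c(4, 8), ]
  yNeg <- 100 - 5 * colSums(adj)
  resNeg <- lagSweep(mk(yNeg), adj, shiftsS = c(4, 8))
  expect_false(resNeg@reliableLag[1, 1, 1])
  expect_lte(resNeg@tstat[1, 1, 1], 0)
})

test_that("activation stats are invariant to positive rescaling of the data", {
  ph <- noiselessPhantom()
  truth <- ph$truth
  e2 <- asVoxelSeries(ph$series, 2L)
  bank <- buildRegressorBank(protocolParadigm())
  brain <- truth@gmMask | truth@wmMask
  r1 <- lagSweep(e2, bank, mask = brain)
  e2scaled <- e2
  e2scaled@data <- e2@data * 3.7
  r2 <- lagSweep(e2scaled, bank, mask = brain)
  expect_equal(r2@tstat[brain], r1@tstat[brain], tolerance = 1e-8)
  expect_equal(r2@beta[brain], 3.7 * r1@beta[brain], tolerance = 1e-8)
  # CVR unchanged because baseline scales identically
  cvr1 <- cvrMap(r1, baselineMap(e2, r1, "mean"))
  cvr2 <- cvrMap(r2, baselineMap(e2scaled, r2, "mean"))
  expect_equal(cvr2[brain], cvr1[brain], tolerance = 1e-8)
})

test_that("activation threshold follows the Student quantile", {
  dims <- c(3L, 1L, 1L)
  res <- new("ActivationResult", beta = array(1, dims),
             tstat = array(c(3.1, 3.3, 0), dims), lagS = array(0, dims),
             r2 = array(0.5, dims), intercept = array(1, dims), dof = 60,
             fitted = array(0, c(dims, 2L)),
             reliableLag = array(TRUE, dims),
             activeMask = array(FALSE, dims), pThreshold = 0.001,
             mask = array(TRUE, dims))
  # one-sided p < 0.001 at 60 dof sits between t = 3.1 and t = 3.3
  act <- thresholdActivation(res, 0.001)
  expect_equal(as.vector(act), c(FALSE, TRUE, FALSE))
  expect_equal(stats::qt(0.999, 60), 3.232, tolerance = 1e-3)

  gm <- array(TRUE, dims)
  expect_equal(fractionActive(act, gm), 1 / 3)
  expect_equal(fractionActive(array(FALSE, dims), gm), 0)
  expect_error(fractionActive(act, array(FALSE, dims)), "empty")
})

test_that("AR(1) prewhitening behaves sensibly on white noise", {
  set.seed(19)
  bank <- buildRegressorBank(protocolParadigm())
  X <- bhDesign(bank@regressors[3, ])
  n <- nrow(X)
  reps <- replicate(60, {
    y <- 50 + rnorm(n)
    pw <- prewhitenAr1(y, X)
    ols <- fitBhGlm(y, X)
    c(rho = pw$rho, dBeta = pw$beta - ols$beta)
  })
  # estimated rho scatters around zero and the fit tracks OLS
  expect_lt(abs(mean(reps["rho", ])), 0.1)
  expect_lt(abs(mean(reps["dBeta", ])), 0.2)
  expect_error(prewhitenAr1(rnorm(5), X[1:5, ]), "frames")
})
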