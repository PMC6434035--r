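mk3 <- function(v, d = c(length(v), 1L, 1L)) array(v, d)

test_that("Dice coefficient identities and hand-counted case", {
  a <- mk3(c(rep(TRUE, 4), rep(FALSE, 6)))
  b <- mk3(c(FALSE, rep(TRUE, 6), rep(FALSE, 3)))
  expect_equal(diceCoefficient(a, a), 1)
  disj <- mk3(c(rep(FALSE, 4), rep(TRUE, 6)))
  expect_equal(diceCoefficient(a, disj), 0)
  # |A| = 4, |B| = 6, overlap = 3 -> 2*3 / 10
  expect_equal(sum(a & b), 3)
  expect_equal(diceCoefficient(a, b), 0.6)
  expect_equal(diceCoefficient(b, a), diceCoefficient(a, b))  # symmetry
  expect_error(diceCoefficient(mk3(rep(FALSE, 4)), mk3(rep(FALSE, 4))),
               "empty")
})

test_that("repeatability index follows its closed form", {
  m1 <- mk3(c(1, 2, 3, 4))
  expect_equal(repeatabilityIndex(m1, m1)$repeatability, 1)
  # x2 = 3 x1 -> 1 - |(-2)/4| = 0.5 at every voxel
  expect_equal(repeatabilityIndex(m1, 3 * m1)$repeatability, 0.5)
  # invariant to common positive rescaling
  expect_equal(repeatabilityIndex(10 * m1, 30 * m1)$repeatability, 0.5)
  # all-zero denominators is an error; partial exclusion is counted
  expect_error(repeatabilityIndex(m1, -m1), "excluded")
  m2 <- 3 * m1
  m2[1, 1, 1] <- -m1[1, 1, 1]
  out <- repeatabilityIndex(m1, m2)
  expect_equal(out$nExcluded, 1L)
  expect_equal(out$repeatability, 0.5)
})

test_that("ICC(3,1) matches a brute-force ANOVA oracle", {
  # identical sessions with subject differences: perfect reliability
  tab <- cbind(c(1, 2, 3, 7), c(1, 2, 3, 7))
  expect_equal(icc31(tab), 1)
  # small table against the ANOVA mean squares from stats::aov
  oracleIcc <- function(tab) {
    df <- data.frame(y = as.vector(tab),
                     subj = factor(rep(seq_len(nrow(tab)), ncol(tab))),
                     sess = factor(rep(seq_len(ncol(tab)), each = nrow(tab))))
    ms <- summary(stats::aov(y ~ subj + sess, data = df))[[1]][, "Mean Sq"]
    bms <- ms[1]
    ems <- ms[3]
    k <- ncol(tab)
    unname((bms - ems) / (bms + (k - 1) * ems))
  }
  tab3 <- cbind(c(1, 2, 3), c(1.1, 2.1, 2.9))
  expect_equal(icc31(tab3), oracleIcc(tab3), tolerance = 1e-10)
  set.seed(4)
  for (i in 1:20) {
    tab <- matrix(rnorm(20), 10, 2) + rnorm(10)
    expect_equal(icc31(tab), oracleIcc(tab), tolerance = 1e-10)
  }
  # no subject effect: near zero on average
  set.seed(5)
  vals <- replicate(200, icc31(matrix(rnorm(100), 50, 2)))
  expect_lt(abs(mean(vals)), 0.1)
  # degenerate inputs
  expect_true(is.na(icc31(matrix(1, 5, 2))))
  expect_error(icc31(matrix(1, 1, 2)), "at least 2")
})

test_that("voxelwise ICC map handles shape and missing cells", {
  set.seed(6)
  vals <- array(rnorm(8 * 2 * 6), c(8, 2, 3, 2, 1))
  m <- icc31Map(vals)
  expect_equal(dim(m), c(3L, 2L, 1L))
  expect_equal(m[1, 1, 1], icc31(vals[, , 1, 1, 1]), tolerance = 1e-12)
  # listwise deletion
  vals[1, 1, 1, 1, 1] <- NA
  m2 <- icc31Map(vals)
  expect_equal(m2[1, 1, 1], icc31(vals[-1, , 1, 1, 1]), tolerance = 1e-12)
})

test_that("spatial correlation and Fisher z", {
  set.seed(7)
  m1 <- mk3(rnorm(1000))
  sc <- spatialCorrelation(m1, 2 * m1 + 1)
  expect_equal(sc$r, 1)
  expect_true(is.infinite(sc$z))
  scN <- spatialCorrelation(m1, mk3(rnorm(1000)))
  expect_lt(abs(scN$r), 2 / sqrt(1000))
  expect_equal(atanh(0.8), 1.0986, tolerance = 1e-4)
  m3 <- mk3(rnorm(1000) + 0.8 * m1)
  sc3 <- spatialCorrelation(m1, m3)
  expect_equal(sc3$z, atanh(sc3$r))
  expect_error(spatialCorrelation(m1, mk3(rep(1, 1000))), "variance")
})

test_that("ICC threshold fractions", {
  gm <- mk3(rep(TRUE, 10))
  expect_equal(unname(iccFractions(mk3(rep(1, 10)), gm)), c(1, 1))
  expect_equal(unname(iccFractions(mk3(rep(0.5, 10)), gm)), c(1, 0))
  set.seed(8)
  u <- mk3(runif(20000))
  expect_equal(unname(iccFractions(u, mk3(rep(TRUE, 20000)))), c(0.6, 0.4),
               tolerance = 0.02)
  expect_error(iccFractions(u, mk3(rep(FALSE, 20000))), "empty")
})

test_that("overlap masks and mask statistics", {
  a <- mk3(c(TRUE, TRUE, FALSE, FALSE))
  b <- mk3(c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(overlapMask(a, b), a)          # a subset of b
  expect_equal(sum(overlapMask(a, !a)), 0L)
  tmap <- mk3(c(2, 4, 9, 1))
  st <- extractStats(tmap, list(gm = b, overlap = a,
                                empty = mk3(rep(FALSE, 4))))
  expect_equal(st$mean[st$mask == "gm"], mean(c(2, 4, 9)))
  expect_equal(st$mean[st$mask == "overlap"], 3)
  expect_equal(st$n[st$mask == "empty"], 0L)
  expect_true(is.na(st$mean[st$mask == "empty"]))
})

test_that("retest report assembles the paired-session metrics", {
  set.seed(9)
  d <- c(6L, 6L, 2L)
  map1 <- array(runif(prod(d), 1, 2), d)
  map2 <- map1 * (1 + 0.1 * rnorm(prod(d)))
  act1 <- array(rep(c(TRUE, FALSE), each = prod(d) / 2), d)
  act2 <- array(rep(c(TRUE, FALSE), times = c(48, 24)), d)
  mask <- array(TRUE, d)
  rep <- retestReport(act1, act2, map1, map2, mask)
  expect_s4_class(rep, "RetestReport")
  expect_equal(rep@dice, diceCoefficient(act1, act2))
  expect_equal(rep@pearsonR, stats::cor(as.vector(map1), as.vector(map2)))
  expect_equal(rep@fisherZ, atanh(rep@pearsonR))
  expect_true(rep@repeatability <= 1)
  expect_equal(sum(rep@overlapMask), sum(act1 & act2))
})
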