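test_that("stationary fixture is exactly self-consistent", {
  st <- makeStationaryFixture()
  expect_true(validObject(st))
  expect_equal(unname(ssb(st)), rep(3200, 10))
  expect_equal(unname(catchN(st)[, 2]), rep(240, 10))
  expect_equal(unname(totalAbundance(st)), rep(2200, 10))
  # every year's column identical
  expect_true(all(apply(abundance(st), 2, function(x) length(unique(x)) == 1)))
})

test_that("geometric fixture scales totals by the ratio with constant age structure", {
  g <- makeGeometricFixture(2, nYears = 3)
  expect_equal(unname(totalAbundance(g)), c(1000, 2000, 4000))
  props <- sweep(abundance(g), 1, totalAbundance(g), `/`)
  expect_true(all(apply(props, 2, function(x) diff(range(x)) < 1e-12)))

  gHalf <- makeGeometricFixture(0.5, nYears = 4)
  tot <- unname(totalAbundance(gHalf))
  expect_equal(tot[-1] / tot[-4], rep(0.5, 3))

  # ratio 1 degenerates to a stationary table
  g1 <- makeGeometricFixture(1, nYears = 5)
  expect_true(all(apply(abundance(g1), 2, function(x) diff(range(x)) == 0)))
  expect_error(makeGeometricFixture(-1), "positive")
})

test_that("generator is deterministic given the seed", {
  cfg <- SimConfig(nYears = 15, seed = 11)
  a <- generateStock(cfg)
  b <- generateStock(cfg)
  expect_identical(abundance(a), abundance(b))
  expect_identical(catchN(a), catchN(b))
  c2 <- generateStock(SimConfig(nYears = 15, seed = 12))
  expect_false(identical(abundance(a), abundance(c2)))
})

test_that("generated cohorts conserve numbers exactly", {
  cfg <- SimConfig(nYears = 20, seed = 3)
  st <- generateStock(cfg)
  N <- abundance(st)
  C <- catchN(st)
  M <- natMortality(st)
  ny <- nrow(N)
  k <- ncol(N)
  deaths <- M * N
  # survivors + catch + natural deaths == previous numbers
  expect_equal(N[2:ny, 2:k] + C[1:(ny - 1), 1:(k - 1)] + deaths[1:(ny - 1), 1:(k - 1)],
               N[1:(ny - 1), 1:(k - 1)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero-noise replacement-level generator reaches the stationary limit", {
  # survival-decayed first-year column plus recruits at replacement rate
  agevec <- 1:4
  m <- rep(0.2, 4)
  f <- c(0, 0.2, 0.3, 0.3)
  w <- c(0.5, 1, 2, 3)
  mat <- c(0, 0.5, 1, 1)
  surv <- 1 - m - f
  n1 <- 1000 * cumprod(c(1, surv[-4]))
  replacementRps <- 1000 / sum(w * mat * n1)
  cfg <- SimConfig(nYears = 12, firstAge = 1, maxAge = 4,
                   recruitsPerKgMean = replacementRps, recruitmentCv = 0,
                   largeEventProb = 0, mAtAge = m, fSelectivity = f,
                   weightAtAge = w, maturityAtAge = mat,
                   initialAbundance = 1000, seed = 1)
  st <- generateStock(cfg)
  expect_true(all(apply(abundance(st), 2,
                        function(x) diff(range(x)) < 1e-8 * max(x))))
})

test_that("recruitment with large events is right-skewed (mean above median)", {
  cfg <- SimConfig(nYears = 50, recruitmentCv = 0.6, largeEventProb = 0.1,
                   largeEventMultiplier = 8, seed = 21)
  st <- generateStock(cfg)
  recruits <- abundance(st)[, 1]
  expect_gt(mean(recruits), median(recruits))
})

test_that("invalid simulation configs are rejected", {
  expect_error(SimConfig(mAtAge = 0.8, fSelectivity = rep(0.3, 10)), "< 1")
  expect_error(SimConfig(largeEventProb = 1.5), "\\[0, 1\\]")
  expect_error(SimConfig(largeEventMultiplier = 0.5), ">= 1")
  expect_error(SimConfig(maxAge = 10, weightAtAge = c(1, 2)), "entries")
})

test_that("StockTable validity catches impossible panels", {
  st <- makeStationaryFixture()
  expect_error(StockTable(stockId = "bad", years = years(st), ages = ages(st),
                          N = abundance(st), C = abundance(st) + 1,
                          W = weightAtAge(st), Mat = maturity(st),
                          M = natMortality(st)),
               "catch exceeds abundance")
  expect_error(StockTable(stockId = "bad", years = c(2001L, 2003L, 2004L),
                          ages = 1:2, N = matrix(1, 3, 2), C = matrix(0, 3, 2),
                          W = matrix(1, 3, 2), Mat = matrix(1, 3, 2),
                          M = matrix(0.1, 3, 2)),
               "increasing by 1")
})
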