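test_that("single reproductive age collapses the renewal equation to s*f", {
  lt <- makeBareLifeTable(l = 0.5, fec = 2)    # one age, s = 1, f = 2
  expect_equal(solveLambda(lt), 2, tolerance = 1e-10)
  # two ages, reproduction only at age 2: lambda^2 = s2 * f2
  lt2 <- makeBareLifeTable(l = c(0.6, 0.5), fec = c(0, 3))
  expect_equal(solveLambda(lt2), sqrt(0.6 * 3), tolerance = 1e-10)
})

test_that("fixture roots match hand-derived values on both bases", {
  st <- makeStationaryFixture()
  lt <- buildLifeTable(st, 2004)
  expect_equal(solveLambda(lt, includeFishing = TRUE), 1, tolerance = 1e-9)
  expect_equal(solveLambda(lt, includeFishing = FALSE), FIX$lambdaDem,
               tolerance = 1e-9)
})

test_that("root equals Leslie-matrix dominant eigenvalue on random life tables", {
  set.seed(4711)
  relDiff <- replicate(200, {
    lt <- randomLifeTable()
    root <- solveLambda(lt)
    abs(root - leslieDominant(lt@l, lt@fec)) / root
  })
  expect_lt(max(relDiff), 1e-8)
})

test_that("no reproduction raises an informative error", {
  lt <- makeBareLifeTable(l = c(0.5, 0.5), fec = c(0, 1))
  lt@fec <- c(0, 0)
  expect_error(solveLambda(lt), "no reproduction")
})

test_that("calibration is a fixed point on self-consistent fixtures", {
  st <- makeStationaryFixture()
  cal <- calibrateYear(st, 2004)
  expect_true(cal$converged)
  expect_equal(cal$nIterations, 0L)
  expect_equal(cal$adjustmentM, 1)
  expect_equal(cal$adjustmentF, 1)
  expect_equal(cal$lambdaReal, 1, tolerance = 1e-9)
})

test_that("calibration walks lambda to the observed abundance ratio", {
  # stationary-shaped schedules with totals doubling each year: the initial
  # schedules under-predict and calibration must raise fecundity / lower M
  st <- makeStationaryFixture()
  scale <- 2^(seq_len(10) - 1)
  stMis <- StockTable(stockId = "mismatch", years = years(st), ages = ages(st),
                      N = abundance(st) * scale, C = catchN(st) * scale,
                      W = weightAtAge(st), Mat = maturity(st),
                      M = natMortality(st))
  cfg <- CalibrationConfig(tolerance = 0.05, step = 0.005)
  cal <- calibrateYear(stMis, 2004, cfg)
  expect_true(cal$converged)
  expect_gt(cal$nIterations, 0)
  expect_true(abs(cal$lambdaReal - 2) / 2 <= cfg$tolerance + 1e-9)
  expect_true(cal$adjustmentF > 1 || cal$adjustmentM < 1)

  # tighter tolerance lands closer and needs at least as many steps
  cfgT <- CalibrationConfig(tolerance = 0.001, step = 0.0005)
  calT <- calibrateYear(stMis, 2004, cfgT)
  expect_true(calT$converged)
  expect_lt(abs(calT$lambdaReal - 2) / 2, 0.0015)
  expect_gte(calT$nIterations, cal$nIterations)
})

test_that("lambda series covers all years but the terminal one", {
  st <- makeStationaryFixture()
  ls1 <- lambdaSeries(st)
  expect_equal(ls1@years, 2001:2009)
  expect_true(all(ls1@converged))
  expect_equal(ls1@lambdaReal, rep(1, 9), tolerance = 1e-9)
  expect_equal(ls1@lambdaDem, rep(FIX$lambdaDem, 9), tolerance = 1e-9)
  expect_equal(ls1@rReal, log(ls1@lambdaReal))

  # shrinking fixture: all realized rates near 0.5
  g <- makeGeometricFixture(0.5, nYears = 6)
  lsG <- lambdaSeries(g, CalibrationConfig(tolerance = 0.001, step = 0.0005))
  expect_true(all(abs(lsG@lambdaReal - 0.5) / 0.5 <= 0.001 + 1e-9))
})

test_that("without fishing the realized and fishing-excluded rates coincide", {
  st <- makeStationaryFixture()
  st0 <- StockTable(stockId = "nofish", years = years(st), ages = ages(st),
                    N = abundance(st), C = matrix(0, 10, 3),
                    W = weightAtAge(st), Mat = maturity(st),
                    M = natMortality(st))
  ls0 <- lambdaSeries(st0)
  expect_equal(ls0@lambdaReal, ls0@lambdaDem, tolerance = 1e-9)
})

test_that("fishing-excluded lambda dominates realized lambda on random stocks", {
  for (seed in 1:5) {
    st <- generateStock(SimConfig(nYears = 18, seed = seed))
    ls1 <- lambdaSeries(st)
    ok <- ls1@converged
    expect_true(all(ls1@lambdaDem[ok] >= ls1@lambdaReal[ok] - 1e-8))
    expect_true(all(abs(ls1@predError[ok]) <= 0.05 + 1e-12))
  }
})

test_that("calibrated series respect the extremal-abundance bounds", {
  # at an interior maximum the next year cannot be higher, so lambda <= 1 + tol;
  # at an interior minimum lambda >= 1 - tol
  for (seed in c(2, 9)) {
    st <- generateStock(SimConfig(nYears = 25, seed = seed))
    ls1 <- lambdaSeries(st)
    tot <- totalAbundance(st)
    tol <- 0.05
    yMax <- years(st)[which.max(tot)]
    iMax <- match(yMax, ls1@years)
    if (!is.na(iMax) && ls1@converged[iMax])
      expect_lte(ls1@lambdaReal[iMax], 1 + tol + 1e-9)
    yMin <- years(st)[which.min(tot)]
    iMin <- match(yMin, ls1@years)
    if (!is.na(iMin) && ls1@converged[iMin])
      expect_gte(ls1@lambdaReal[iMin], 1 - tol - 1e-9)
  }
})
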