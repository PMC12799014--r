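test_that("recruitment rate is recruits over lagged spawning biomass", {
  st <- makeStationaryFixture()
  expect_equal(recruitmentRate(st, 2005), 1000 / 3200)
  # linearity: doubling recruits with SSB fixed doubles RPS
  st2 <- st
  st2@N[5, 1] <- 2000   # age 1 is immature, SSB unchanged
  expect_equal(recruitmentRate(st2, years(st2)[5]), 2 * 0.3125)
  # zero recruits observed
  st2@N[5, 1] <- 0
  st2@C[5, 1] <- 0
  expect_equal(recruitmentRate(st2, years(st2)[5]), 0)
  expect_error(recruitmentRate(st, 2001 - 1), "outside")
})

test_that("fecundity equals weight times RPS on mature ages, zero elsewhere", {
  st <- makeStationaryFixture()
  fy <- fecundityAtAge(st, 2004)
  expect_equal(fy$fec, FIX$fec)
  expect_equal(fy$rpa, c(0, 500, 500))
  expect_equal(fy$ns, c(0, 800, 400))
  # attribution conserves recruits: sum(fec * ns) = next year's recruit count
  expect_equal(sum(fy$fec * fy$ns), 1000)
  # intermediate: RPA at age 2 is its spawning biomass times RPS
  expect_equal(fy$rpa[2], 1600 * 0.3125)

  # all-immature stock has zero fecundity everywhere
  stImm <- StockTable(stockId = "imm", years = years(st), ages = ages(st),
                      N = abundance(st), C = catchN(st), W = weightAtAge(st),
                      Mat = matrix(0, 10, 3), M = natMortality(st))
  expect_error(fecundityAtAge(stImm, 2004), "zero")  # SSB = 0: rate undefined
})

test_that("per-capita basis scales per-spawner fecundity by maturity", {
  st <- makeStationaryFixture()
  st@Mat[, 2] <- 0.5  # partial maturity at age 2, every year
  perSpawner <- fecundityAtAge(st, 2004, basis = "perSpawner")$fec
  perCapita <- fecundityAtAge(st, 2004, basis = "perCapita")$fec
  expect_equal(perCapita, perSpawner * c(0, 0.5, 1))
})

test_that("mortality decomposition recovers F, Z and clamped survival", {
  st <- makeStationaryFixture()
  mt <- mortalityAtAge(st, 2003)
  expect_equal(mt$f, c(0, 0.3, 0.3))
  expect_equal(mt$z, c(0.2, 0.5, 0.5))
  expect_equal(mt$l, FIX$lReal)

  # no fishing: Z = M
  st0 <- st
  st0@C[] <- 0
  mt0 <- mortalityAtAge(st0, 2003)
  expect_equal(mt0$z, rep(0.2, 3))
  expect_equal(mt0$l, rep(0.8, 3))

  # catch equal to abundance: Z >= 1, survival clamped with a flag
  stx <- st
  stx@C[3, 3] <- stx@N[3, 3]
  mtx <- mortalityAtAge(stx, years(st)[3])
  expect_equal(mtx$l[3], 1e-6)
  expect_match(paste(mtx$flags, collapse = " "), "clamped")
})

test_that("survivorship is the cumulative product of prior survival", {
  expect_equal(survivorshipToAge(FIX$lReal), FIX$sReal)
  expect_equal(survivorshipToAge(FIX$lDem), FIX$sDem)
  expect_equal(survivorshipToAge(rep(1, 5)), rep(1, 5))
  expect_error(survivorshipToAge(numeric(0)), "empty")
  expect_error(survivorshipToAge(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("assembled life table satisfies its invariants on the fixture", {
  st <- makeStationaryFixture()
  lt <- buildLifeTable(st, 2004)
  expect_s4_class(lt, "LifeTable")
  expect_equal(lt@nu, 2L)
  expect_equal(lt@omega, 3L)
  expect_equal(lt@fec, FIX$fec)
  expect_equal(lt@sReal, FIX$sReal)
  expect_equal(lt@sDem, FIX$sDem)
  expect_true(all(lt@sReal <= lt@sDem))

  # without fishing the two survivorship schedules coincide
  st0 <- st
  st0@C[] <- 0
  lt0 <- buildLifeTable(st0, 2004)
  expect_equal(lt0@sReal, lt0@sDem)

  # identical across years for the stationary fixture
  lt2 <- buildLifeTable(st, 2006)
  expect_equal(lt2@fec, lt@fec)
  expect_equal(lt2@sReal, lt@sReal)
})

test_that("schedule years require a successor and a lagged parental year", {
  st <- makeStationaryFixture()            # b = 1, years 2001-2010
  expect_equal(scheduleYears(st), 2001:2009)
  expect_error(buildLifeTable(st, 2010), "outside")
})

test_that("backfill reconstructs younger ages by inverting survival", {
  # two-age stock starting at age 2 built so the age-1 answer is known:
  # N(y-1, 1) = N(y, 2) / (1 - M)
  ny <- 6
  yrs <- 2001:2006
  N <- matrix(c(800, 300), ny, 2, byrow = TRUE)
  st <- StockTable(stockId = "b2", years = yrs, ages = 2:3,
                   N = N, C = N * 0.1, W = matrix(c(2, 4), ny, 2, byrow = TRUE),
                   Mat = matrix(c(1, 1), ny, 2, byrow = TRUE),
                   M = matrix(0.2, ny, 2))
  bf <- backfillYoungAges(st)
  expect_equal(ages(bf), 1:3)
  expect_equal(unname(abundance(bf)[1, 1]), 800 / 0.8)
  expect_equal(unname(catchN(bf)[, 1]), rep(0, ny))
  expect_equal(bf@metadata$backfilledAges, 1L)
  # b = 1 input is a no-op
  st1 <- makeStationaryFixture()
  expect_message(out <- backfillYoungAges(st1), "nothing to backfill")
  expect_identical(abundance(out), abundance(st1))
})

test_that("backfilled stationary-like stock changes lambda only slightly", {
  # stationary 3-age stock observed only from age 2 upward
  ny <- 12
  N <- matrix(c(800, 400), ny, 2, byrow = TRUE)
  st <- StockTable(stockId = "b2s", years = seq(2001, length.out = ny),
                   ages = 2:3, N = N, C = sweep(N, 2, c(0.3, 0.3), `*`),
                   W = matrix(c(2, 4), ny, 2, byrow = TRUE),
                   Mat = matrix(1, ny, 2), M = matrix(0.2, ny, 2))
  lsOrig <- lambdaSeries(st)
  lsBack <- lambdaSeries(backfillYoungAges(st))
  common <- intersect(lsOrig@years, lsBack@years)
  iO <- match(common, lsOrig@years)
  iB <- match(common, lsBack@years)
  # both calibrate the same totals ratio; the stationary case stays at 1
  expect_equal(lsBack@lambdaReal[iB], lsOrig@lambdaReal[iO], tolerance = 1e-6)
  expect_equal(lsBack@lambdaDem[iB], lsOrig@lambdaDem[iO], tolerance = 0.1)
})
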