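test_that("stock tables round-trip through the CSV schema", {
  st <- makeStationaryFixture()
  tf <- withr::local_tempfile(fileext = ".csv")
  writeStockTable(st, tf)
  back <- readStockTable(tf)
  expect_equal(abundance(back), abundance(st))
  expect_equal(catchN(back), catchN(st))
  expect_equal(natMortality(back), natMortality(st))
  expect_equal(stockId(back), stockId(st))
})

test_that("the reader rejects malformed panels with row coordinates", {
  st <- makeStationaryFixture()
  df <- as.data.frame(st)
  tf <- withr::local_tempfile(fileext = ".csv")

  bad <- df
  bad$catch_n[12] <- bad$abundance_n[12] + 5
  utils::write.csv(bad, tf, row.names = FALSE)
  expect_error(readStockTable(tf), "catch exceeds abundance at row\\(s\\) 12")

  bad <- df[df$year != 2004, ]
  utils::write.csv(bad, tf, row.names = FALSE)
  expect_error(readStockTable(tf), "not contiguous")

  bad <- df[, setdiff(names(df), "m_annual")]
  utils::write.csv(bad, tf, row.names = FALSE)
  expect_error(readStockTable(tf), "m_annual")

  bad <- df
  bad$abundance_n[3] <- -1
  utils::write.csv(bad, tf, row.names = FALSE)
  expect_error(readStockTable(tf), "negative")
})

test_that("simulation configs parse from key-value text", {
  tf <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# demo config", "n_years = 12", "max_age = 4",
               "m_at_age = 0.2, 0.2, 0.25, 0.3",
               "recruitment_cv = 0", "large_event_prob = 0", "seed = 5"), tf)
  cfg <- readSimConfig(tf)
  expect_equal(cfg$nYears, 12L)
  expect_equal(cfg$mAtAge, c(0.2, 0.2, 0.25, 0.3))
  expect_equal(cfg$recruitmentCv, 0)
  writeLines("bogus_key = 1", tf)
  expect_error(readSimConfig(tf), "unknown config key")
})

test_that("decade summary reproduces closed-form constant and two-point cases", {
  st <- makeStationaryFixture()       # 2001-2010, lambda_real = 1 every year
  ls1 <- lambdaSeries(st)
  tab <- decadeSummary(list(ls1), list(st))
  expect_equal(tab$decade, c(2000, 2010)[seq_len(nrow(tab))])
  d2000 <- tab[tab$decade == 2000, ]
  expect_equal(d2000$lambda_real_median, 1, tolerance = 1e-9)
  expect_equal(d2000$lambda_real_mean, 1, tolerance = 1e-9)
  expect_equal(d2000$lambda_real_sd, 0, tolerance = 1e-9)
  expect_equal(d2000$lambda_dem_median, FIX$lambdaDem, tolerance = 1e-9)
  expect_equal(d2000$n_stocks, 1L)
  expect_equal(d2000$prop_max_median, 1)

  # median of r is the median of the logs: equal counts of 0.5 and 2 give
  # median lambda 1.25 but median r exactly 0
  idx <- 1:8
  fake <- ls1
  fake@years <- ls1@years[idx]
  fake@lambdaReal <- rep(c(0.5, 2), 4)
  fake@lambdaDem <- fake@lambdaReal
  fake@rReal <- log(fake@lambdaReal)
  fake@rDem <- fake@rReal
  fake@converged <- ls1@converged[idx]
  fake@nIterations <- ls1@nIterations[idx]
  fake@adjustmentM <- ls1@adjustmentM[idx]
  fake@adjustmentF <- ls1@adjustmentF[idx]
  fake@predError <- ls1@predError[idx]
  fake@lifeTables <- ls1@lifeTables[idx]
  tab2 <- decadeSummary(list(fake), list(st))
  d <- tab2[tab2$decade == 2000, ]
  expect_equal(d$lambda_real_median, 1.25)
  expect_equal(d$r_real_median, 0, tolerance = 1e-12)
})

test_that("group variability averages per-stock SDs within groups", {
  st <- makeStationaryFixture()
  ls1 <- lambdaSeries(st)
  ls2 <- ls1
  ls2@stockId <- "FIX-STAT-2"
  groups <- c("FIX-STAT" = "fixture:stat", "FIX-STAT-2" = "fixture:stat")
  tab <- groupVariability(list(ls1, ls2), groups)
  expect_equal(tab$n_stocks, 2L)
  expect_equal(tab$mean_sd, 0, tolerance = 1e-9)  # identical constant series
  expect_equal(tab$sd_sd, 0, tolerance = 1e-9)

  # alternating 0.9 / 1.1 series has the closed-form two-point sample SD
  alt <- ls1
  alt@stockId <- "alt"
  alt@lambdaDem <- rep(c(0.9, 1.1), length.out = 9)
  twoPointSd <- sd(rep(c(0.9, 1.1), length.out = 9))
  tabAlt <- groupVariability(list(alt), c(alt = "solo"))
  expect_equal(tabAlt$mean_sd, twoPointSd)
  expect_true(is.na(tabAlt$sd_sd))       # singleton group has no spread

  expect_warning(groupVariability(list(ls1), c("FIX-STAT" = "a", ghost = "b")),
                 "omitted")
  expect_error(groupVariability(list(ls1), c(other = "x")), "no group label")
})

test_that("the pipeline runs end to end, deterministically, with a manifest", {
  stocks <- lapply(1:3, function(i)
    generateStock(SimConfig(nYears = 18, seed = 30 + i),
                  stockId = paste0("sim", i)))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  rec <- RecoveryConfig(nSims = 50, seed = 7)
  res <- runPipeline(stocks, out1, recovery = rec)
  expect_named(res, c("series", "cohorts", "ddFits", "recovery", "decades",
                      "variability", "manifest"))
  expect_equal(res$manifest$n_stocks, 3)
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "lambda_sim1.csv")))
  expect_true(file.exists(file.path(out1, "recovery_classes.csv")))
  expect_true(file.exists(file.path(out1, "dd_anchors_dem.csv")))

  runPipeline(stocks, out2, recovery = rec)
  for (f in c("lambda_sim1.csv", "cohort_metrics.csv", "decade_summary.csv",
              "doubling_sim2.csv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }

  expect_error(runPipeline("no/such/file.csv", withr::local_tempdir()),
               "do not exist")
})
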