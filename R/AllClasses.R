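#' @import methods
NULL

#' StockTable: a year-by-age panel of stock-assessment output
#'
#' The central input container of the package. A \code{StockTable} holds, for
#' one stock, the year-by-age matrices a statistical catch-at-age assessment
#' reports: estimated numbers-at-age, fishery removals in numbers, mean
#' individual weight (kg), maturity proportion, and the annual natural
#' mortality proportion. Rows are consecutive calendar years, columns are
#' consecutive integer ages from the recruit age \code{b} to the terminal age
#' \code{omega}; the terminal age is treated as true longevity (no plus
#' group).
#'
#' Validity requires all five matrices to share the same year-by-age shape,
#' \code{N >= 0}, \code{C >= 0}, \code{C <= N} elementwise (the fishery cannot
#' remove more fish than exist), \code{W > 0}, maturity in [0, 1], natural
#' mortality in [0, 1), and years strictly increasing by 1.
#'
#' @slot stockId single character label identifying the stock.
#' @slot species species label.
#' @slot region region label.
#' @slot years integer vector of consecutive calendar years (row order).
#' @slot ages integer vector of consecutive ages b..omega (column order).
#' @slot N numbers-at-age matrix (year x age).
#' @slot C catch-numbers-at-age matrix (year x age).
#' @slot W mean weight-at-age matrix, kg (year x age).
#' @slot Mat maturity-proportion matrix (year x age).
#' @slot M annual natural-mortality-proportion matrix (year x age).
#' @slot metadata list of free-form annotations (e.g. backfill provenance).
#'
#' @seealso [StockTable()] for the constructor, [generateStock()],
#'   [makeStationaryFixture()], [readStockTable()].
#' @export
setClass("StockTable",
  representation(
    stockId  = "character",
    species  = "character",
    region   = "character",
    years    = "integer",
    ages     = "integer",
    N        = "matrix",
    C        = "matrix",
    W        = "matrix",
    Mat      = "matrix",
    M        = "matrix",
    metadata = "list"
  )
)

setValidity("StockTable", function(object) {
  msg <- character()
  ny <- length(object@years)
  na <- length(object@ages)
  mats <- list(N = object@N, C = object@C, W = object@W,
               Mat = object@Mat, M = object@M)
  for (nm in names(mats)) {
    if (!identical(dim(mats[[nm]]), c(ny, na)))
      msg <- c(msg, sprintf("matrix '%s' must be %d years x %d ages", nm, ny, na))
  }
  if (length(msg)) return(msg)
  if (ny > 1 && any(diff(object@years) != 1L))
    msg <- c(msg, "years must be strictly increasing by 1")
  if (na > 1 && any(diff(object@ages) != 1L))
    msg <- c(msg, "ages must be consecutive integers")
  if (any(!is.finite(object@N)) || any(object@N < 0))
    msg <- c(msg, "N must be finite and >= 0")
  if (any(!is.finite(object@C)) || any(object@C < 0))
    msg <- c(msg, "C must be finite and >= 0")
  bad <- which(object@C > object@N * (1 + 1e-12), arr.ind = TRUE)
  if (nrow(bad) > 0)
    msg <- c(msg, sprintf("catch exceeds abundance at year %s age %s",
                          object@years[bad[1, 1]], object@ages[bad[1, 2]]))
  if (any(!is.finite(object@W)) || any(object@W <= 0))
    msg <- c(msg, "W must be finite and > 0")
  if (any(object@Mat < 0) || any(object@Mat > 1))
    msg <- c(msg, "Mat must lie in [0, 1]")
  if (any(object@M < 0) || any(object@M >= 1))
    msg <- c(msg, "M must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' LifeTable: one stock-year's reconstructed demographic schedule
#'
#' A period (cross-sectional) life table for a single calendar year:
#' fecundity-at-age (recruits per spawner), fishing/natural/total mortality
#' proportions, survival-at-age, and cumulative survivorship-to-age both
#' including fishing (\code{sReal}, built from Z = F + M) and excluding it
#' (\code{sDem}, built from M only). Survivorship to the first age class is
#' fixed at 1. When produced by [calibrateYear()]/[lambdaSeries()], the
#' \code{m} and \code{fec} slots carry the calibration-adjusted rates.
#'
#' @slot stockId stock label.
#' @slot year calendar year of the schedule.
#' @slot ages integer ages b..omega.
#' @slot rps recruits per kg of spawning biomass feeding this year's schedule.
#' @slot rpa recruits attributed to each age class.
#' @slot ns spawner numbers per age class.
#' @slot fec fecundity-at-age: recruits per spawner.
#' @slot f fishing mortality proportion at age (catch / numbers).
#' @slot m natural mortality proportion at age.
#' @slot z total mortality proportion at age (possibly >= 1; see \code{l}).
#' @slot l survival-at-age, 1 - Z clamped to a small positive floor.
#' @slot sReal survivorship-to-age including fishing.
#' @slot sDem survivorship-to-age excluding fishing.
#' @slot nu age at first reproduction (youngest age with fec > 0; NA if none).
#' @slot omega terminal age.
#' @slot deltaX census interval in years (always 1).
#' @slot flags character vector of warnings raised during construction.
#'
#' @seealso [buildLifeTable()], [solveLambda()]
#' @export
setClass("LifeTable",
  representation(
    stockId = "character",
    year    = "integer",
    ages    = "integer",
    rps     = "numeric",
    rpa     = "numeric",
    ns      = "numeric",
    fec     = "numeric",
    f       = "numeric",
    m       = "numeric",
    z       = "numeric",
    l       = "numeric",
    sReal   = "numeric",
    sDem    = "numeric",
    nu      = "integer",
    omega   = "integer",
    deltaX  = "numeric",
    flags   = "character"
  )
)

setValidity("LifeTable", function(object) {
  msg <- character()
  k <- length(object@ages)
  for (nm in c("rpa", "ns", "fec", "f", "m", "z", "l", "sReal", "sDem")) {
    if (length(slot(object, nm)) != k)
      msg <- c(msg, sprintf("'%s' must have one entry per age", nm))
  }
  if (length(msg)) return(msg)
  if (k > 0) {
    if (abs(object@sReal[1] - 1) > 1e-12 || abs(object@sDem[1] - 1) > 1e-12)
      msg <- c(msg, "survivorship to the first age class must be 1")
    if (any(object@sReal > object@sDem + 1e-12))
      msg <- c(msg, "sReal must not exceed sDem")
    if (any(diff(object@sReal) > 1e-12) || any(diff(object@sDem) > 1e-12))
      msg <- c(msg, "survivorship must be nonincreasing with age")
    if (any(object@l <= 0) || any(object@l > 1))
      msg <- c(msg, "survival-at-age must lie in (0, 1]")
    if (any(object@fec < 0))
      msg <- c(msg, "fecundity must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' LambdaSeries: calibrated annual population growth rates for one stock
#'
#' Per-year realized growth rate (\code{lambdaReal}, fishing included) and
#' fishing-excluded growth rate (\code{lambdaDem}), both solved from the
#' discrete Euler-Lotka equation after the iterative abundance-matching
#' calibration, together with convergence diagnostics and the calibrated
#' per-year [LifeTable-class] objects used downstream. The terminal data year
#' has no entry: it has no successor to calibrate against.
#'
#' @slot stockId stock label.
#' @slot years calendar years with a calibrated schedule.
#' @slot lambdaReal realized annual growth rate (fishing included).
#' @slot lambdaDem fishing-excluded annual growth rate.
#' @slot rReal log lambdaReal.
#' @slot rDem log lambdaDem.
#' @slot converged logical; did calibration reach tolerance.
#' @slot nIterations calibration step count per year.
#' @slot adjustmentM net multiplicative adjustment applied to M-at-age.
#' @slot adjustmentF net multiplicative adjustment applied to fecundity-at-age.
#' @slot predError per-year relative difference (lambda * Ny - Ny1) / Ny1.
#' @slot lifeTables list of calibrated [LifeTable-class]s, one per year.
#'
#' @seealso [lambdaSeries()], [calibrateYear()]
#' @export
setClass("LambdaSeries",
  representation(
    stockId     = "character",
    years       = "integer",
    lambdaReal  = "numeric",
    lambdaDem   = "numeric",
    rReal       = "numeric",
    rDem        = "numeric",
    converged   = "logical",
    nIterations = "integer",
    adjustmentM = "numeric",
    adjustmentF = "numeric",
    predError   = "numeric",
    lifeTables  = "list"
  )
)

setValidity("LambdaSeries", function(object) {
  msg <- character()
  n <- length(object@years)
  for (nm in c("lambdaReal", "lambdaDem", "rReal", "rDem", "converged",
               "nIterations", "adjustmentM", "adjustmentF", "predError")) {
    if (length(slot(object, nm)) != n)
      msg <- c(msg, sprintf("'%s' must have one entry per year", nm))
  }
  if (length(msg)) return(msg)
  ok <- !is.na(object@lambdaReal)
  if (any(object@lambdaReal[ok] <= 0))
    msg <- c(msg, "lambdaReal must be positive")
  okd <- ok & !is.na(object@lambdaDem)
  if (any(object@lambdaDem[okd] < object@lambdaReal[okd] - 1e-8))
    msg <- c(msg, "lambdaDem must be >= lambdaReal")
  if (length(msg)) msg else TRUE
})

#' CohortRecord: a complete cohort's demographic schedules and summaries
#'
#' Schedules for one birth cohort, read along the diagonal (year c + x - b,
#' age x) of the calibrated per-year life tables: cohort survivorship under
#' total mortality (\code{sWithF}) and under natural mortality only
#' (\code{sNoF}), cohort fecundity-at-age, and the derived lifetime
#' reproductive success and generation length under both bases. A cohort is
#' \code{complete} when every age from the recruit age to the terminal age is
#' observed within the data span; \code{fullSchedules} additionally records
#' whether a calibrated fecundity schedule exists at every cohort age (the
#' terminal data year has none, so the youngest complete cohort may carry an
#' NA fecundity at its last age, leaving R0 and LG as NA).
#'
#' @slot stockId stock label.
#' @slot cohortYear calendar year in which the cohort appears at the recruit age.
#' @slot ages integer ages b..omega.
#' @slot sWithF cohort survivorship-to-age under Z = F + M.
#' @slot sNoF cohort survivorship-to-age under M only.
#' @slot fec cohort fecundity-at-age (recruits per spawner; NA if unscheduled).
#' @slot r0WithF,r0NoF lifetime reproductive success (spawners per spawner).
#' @slot lgWithF,lgNoF generation length, years.
#' @slot complete all ages observed within the data span.
#' @slot fullSchedules calibrated schedules available at every cohort age.
#'
#' @seealso [extractCompleteCohorts()], [lifetimeReproductiveSuccess()],
#'   [generationLength()]
#' @export
setClass("CohortRecord",
  representation(
    stockId       = "character",
    cohortYear    = "integer",
    ages          = "integer",
    sWithF        = "numeric",
    sNoF          = "numeric",
    fec           = "numeric",
    r0WithF       = "numeric",
    r0NoF         = "numeric",
    lgWithF       = "numeric",
    lgNoF         = "numeric",
    complete      = "logical",
    fullSchedules = "logical"
  )
)

#' DDFit: hierarchical smooth fit of lambda against relative abundance
#'
#' Wraps a penalized-spline model of log(lambda) on the proportion of maximum
#' observed abundance: a global smooth plus per-stock deviation smooths
#' sharing a smoothing penalty (factor-smooth random effects). Carries the
#' fitted \pkg{mgcv} model, the observations, and each stock's minimum
#' observed proportion, from which anchor evaluations (minimum, 40%, maximum
#' abundance) are derived.
#'
#' @slot basis which lambda was modelled: "real" or "dem".
#' @slot model the fitted \code{mgcv::gam} object.
#' @slot data the observation data.frame (stock_id, year, prop, lam).
#' @slot minProp named numeric: minimum observed proportion per stock.
#'
#' @seealso [fitDensityDependence()], [lambdaAtAnchors()], [globalCurve()]
#' @export
setClass("DDFit",
  representation(
    basis   = "character",
    model   = "ANY",
    data    = "data.frame",
    minProp = "numeric"
  )
)

#' RecoveryResult: Monte Carlo doubling-time projection for one stock
#'
#' The per-year proportion of simulated no-fishing trajectories whose
#' relative abundance has reached at least twice its initial value (doubling
#' is absorbing, so the curve is nondecreasing), the per-simulation first
#' doubling year, and the resulting three-way recovery classification.
#'
#' @slot stockId stock label.
#' @slot years projection years 1..horizon.
#' @slot propDoubled proportion of simulations doubled by each year.
#' @slot firstDoubling per-simulation first doubling year (NA if never).
#' @slot classification "high", "moderate", or "low".
#'
#' @seealso [projectDoubling()], [classifyRecovery()]
#' @export
setClass("RecoveryResult",
  representation(
    stockId        = "character",
    years          = "integer",
    propDoubled    = "numeric",
    firstDoubling  = "numeric",
    classification = "character"
  )
)

setValidity("RecoveryResult", function(object) {
  msg <- character()
  if (length(object@propDoubled) != length(object@years))
    msg <- c(msg, "propDoubled must have one entry per projection year")
  else {
    if (any(object@propDoubled < 0) || any(object@propDoubled > 1))
      msg <- c(msg, "propDoubled must lie in [0, 1]")
    if (any(diff(object@propDoubled) < -1e-12))
      msg <- c(msg, "propDoubled must be nondecreasing (doubling is absorbing)")
  }
  if (length(msg)) msg else TRUE
})
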