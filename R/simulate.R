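#' Forward-simulate an age-structured stock-assessment panel
#'
#' Cohort dynamics with proportional (annual) mortality: survivors follow
#' \code{N[y+1, a+1] = N[y, a] * (1 - M[a] - F[a])}, catch is \code{C[y, a] =
#' F[a] * N[y, a]}, and recruits entering at the recruit age b in year y are
#' \code{SSB[y - b] * recruitsPerKgMean * dev}, where \code{dev} is a
#' mean-corrected lognormal deviate (CV \code{recruitmentCv}) multiplied by
#' \code{largeEventMultiplier} with probability \code{largeEventProb}. The
#' first year is seeded with a survival-decayed age structure from
#' \code{initialAbundance}; recruit years whose parental year predates the
#' series use the first year's spawning biomass. The simulation is
#' deterministic given \code{cfg$seed}, and every simulated cohort conserves
#' numbers exactly: survivors + catch + natural deaths = previous numbers.
#'
#' @param cfg a [SimConfig()] object.
#' @param stockId,species,region labels attached to the output.
#' @param yearStart first calendar year of the series.
#' @return a validated [StockTable-class].
#' @examples
#' st <- generateStock(SimConfig(nYears = 25, seed = 42))
#' range(totalAbundance(st))
#' @export
generateStock <- function(cfg, stockId = "sim", species = "Simulatus exemplaris",
                          region = "in silico", yearStart = 1981L) {
  validateSimConfig(cfg)
  agevec <- seq.int(cfg$firstAge, cfg$maxAge)
  k <- length(agevec)
  ny <- cfg$nYears
  yrs <- seq.int(as.integer(yearStart), length.out = ny)
  m <- cfg$mAtAge
  f <- cfg$fSelectivity
  surv <- 1 - m - f

  # recruitment deviates, mean-corrected lognormal x Bernoulli large event
  set.seed(cfg$seed)
  sdlog <- sqrt(log(1 + cfg$recruitmentCv^2))
  devs <- stats::rlnorm(ny, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  events <- stats::runif(ny) < cfg$largeEventProb
  devs[events] <- devs[events] * cfg$largeEventMultiplier

  N <- matrix(0, ny, k)
  N[1, 1] <- cfg$initialAbundance
  if (k > 1) for (a in 2:k) N[1, a] <- N[1, a - 1] * surv[a - 1]
  wmat <- cfg$weightAtAge * cfg$maturityAtAge
  ssbOf <- function(y) sum(wmat * N[y, ])
  for (y in seq_len(ny - 1L)) {
    if (k > 1) N[y + 1L, 2:k] <- N[y, 1:(k - 1)] * surv[1:(k - 1)]
    parental <- max(1L, y + 1L - cfg$firstAge)
    N[y + 1L, 1] <- ssbOf(parental) * cfg$recruitsPerKgMean * devs[y + 1L]
    if (any(!is.finite(N[y + 1L, ])))
      stop(sprintf("non-finite abundance simulated in year %d; check SimConfig",
                   yrs[y + 1L]), call. = FALSE)
  }
  C <- sweep(N, 2, f, `*`)
  StockTable(stockId = stockId, species = species, region = region,
             years = yrs, ages = agevec,
             N = N, C = C,
             W = matrix(cfg$weightAtAge, ny, k, byrow = TRUE),
             Mat = matrix(cfg$maturityAtAge, ny, k, byrow = TRUE),
             M = matrix(m, ny, k, byrow = TRUE),
             metadata = list(simulated = TRUE, seed = cfg$seed))
}

#' Exact stationary fixture
#'
#' A three-age stock, identical in every year, whose recruitment, mortality
#' and catch are exactly self-consistent: N = (1000, 800, 400), weight =
#' (1, 2, 4) kg, knife-edge maturity (0, 1, 1), M = 0.2 at all ages and
#' fishing proportions (0, 0.3, 0.3), hence catch (0, 240, 120), 1000
#' recruits per year and a spawning biomass of 3200 kg. Because maturity is
#' knife-edge the reconstructed schedules satisfy the Euler-Lotka equation
#' at lambda = 1 exactly, making this the reference fixture for replacement
#' identities (realized lambda = 1, cohort R0 with fishing = 1).
#'
#' @param nYears number of (identical) years, default 10.
#' @param yearStart first calendar year.
#' @return a [StockTable-class].
#' @examples
#' st <- makeStationaryFixture()
#' stopifnot(all(ssb(st) == 3200))
#' @export
makeStationaryFixture <- function(nYears = 10L, yearStart = 2001L) {
  n <- c(1000, 800, 400)
  f <- c(0, 0.3, 0.3)
  ny <- as.integer(nYears)
  StockTable(stockId = "FIX-STAT", species = "Stationarius testus",
             region = "fixture",
             years = seq.int(as.integer(yearStart), length.out = ny),
             ages = 1:3,
             N = matrix(n, ny, 3, byrow = TRUE),
             C = matrix(n * f, ny, 3, byrow = TRUE),
             W = matrix(c(1, 2, 4), ny, 3, byrow = TRUE),
             Mat = matrix(c(0, 1, 1), ny, 3, byrow = TRUE),
             M = matrix(0.2, ny, 3),
             metadata = list(fixture = "stationary"))
}

#' Exact geometric-growth fixture
#'
#' A stock whose total (and at-age) abundance satisfies \code{N(y+1) = ratio
#' * N(y)} exactly: the stationary fixture's vital rates (weights (1, 2, 4)
#' kg, knife-edge maturity, M = 0.2, fishing (0, 0.3, 0.3)) are paired with
#' the stable age distribution of a population growing at \code{ratio}, so
#' that cohort survival is internally consistent (\code{N[y+1, a+1] =
#' N[y, a] * (1 - M - F)}) while every year's total is \code{ratio} times
#' the previous. With knife-edge maturity the reconstructed schedules solve
#' the Euler-Lotka equation at lambda = ratio exactly, which makes this the
#' fixture of choice for checking the abundance-ratio constraints on
#' calibrated lambda (a year at 1/ratio of the maximum whose successor is
#' the maximum must calibrate to lambda = ratio).
#'
#' @param ratio year-over-year multiplier of total abundance (> 0);
#'   \code{ratio = 1} reproduces a stationary table.
#' @param nYears series length, default 6.
#' @param initialTotal total abundance (all ages) in the first year.
#' @param yearStart first calendar year.
#' @return a [StockTable-class].
#' @examples
#' st <- makeGeometricFixture(2, nYears = 3)
#' totalAbundance(st)   # 1000 2000 4000
#' @export
makeGeometricFixture <- function(ratio, nYears = 6L, initialTotal = 1000,
                                 yearStart = 2001L) {
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) ||
      ratio <= 0)
    stop("ratio must be a single positive number", call. = FALSE)
  ny <- as.integer(nYears)
  m <- rep(0.2, 3)
  f <- c(0, 0.3, 0.3)
  surv <- 1 - m - f
  # stable age distribution at growth rate `ratio`
  u <- c(1, surv[1] / ratio, surv[1] * surv[2] / ratio^2)
  u <- u / sum(u) * initialTotal
  N <- outer(ratio^(seq_len(ny) - 1), u)
  C <- sweep(N, 2, f, `*`)
  StockTable(stockId = sprintf("FIX-GEOM-%g", ratio),
             species = "Geometricus testus", region = "fixture",
             years = seq.int(as.integer(yearStart), length.out = ny),
             ages = 1:3,
             N = N, C = C,
             W = matrix(c(1, 2, 4), ny, 3, byrow = TRUE),
             Mat = matrix(c(0, 1, 1), ny, 3, byrow = TRUE),
             M = matrix(m, ny, 3, byrow = TRUE),
             metadata = list(fixture = "geometric", ratio = ratio))
}
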