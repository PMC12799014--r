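#' Annual recruitment rate (recruits per kg of spawning biomass)
#'
#' The number of fish entering the youngest assessed age class in
#' \code{year}, divided by the spawning stock biomass of the parental year
#' \code{year - b}, where b is the recruit age. For a stock whose youngest
#' assessed age is 2, recruits observed in 2010 are attributed to the 2008
#' spawning biomass.
#'
#' @param stock a [StockTable-class].
#' @param year calendar year in which the recruits are observed; the
#'   parental year \code{year - b} must lie within the observed span.
#' @return recruits per kg (scalar).
#' @examples
#' recruitmentRate(makeStationaryFixture(), 2005)   # 1000 / 3200
#' @export
recruitmentRate <- function(stock, year) {
  b <- firstAge(stock)
  iy <- yearIndex(stock, year, "recruit year")
  ip <- yearIndex(stock, year - b, "parental year")
  sb <- ssb(stock)[ip]
  if (sb <= 0)
    stop(sprintf("SSB in parental year %d of stock '%s' is zero; recruitment rate undefined",
                 year - b, stock@stockId), call. = FALSE)
  unname(stock@N[iy, 1] / sb)
}

#' Fecundity-at-age for one stock-year
#'
#' Recruits per spawner in each age class, built by biomass-proportional
#' attribution: the recruits observed in \code{year + 1} are first converted
#' to a rate per kg of parental spawning biomass, each age class is credited
#' with recruits in proportion to its spawning biomass, and the credited
#' recruits are divided by the spawner numbers (maturity x abundance) of the
#' attribution year \code{year + 1 - b}. Ages with no spawners have
#' fecundity 0 by convention. Under this attribution, fecundity for mature
#' ages equals weight-at-age times the recruitment rate exactly. Fecundity
#' is offset by one year: recruits observed in \code{year + 1} enter the
#' Euler-Lotka formulation of \code{year}.
#'
#' @param stock a [StockTable-class].
#' @param year calendar year of the schedule; both \code{year + 1} and
#'   \code{year + 1 - b} must lie within the observed span.
#' @param basis \code{"perSpawner"} (recruits per mature spawner, the
#'   default) or \code{"perCapita"} (multiplied by maturity, recruits per
#'   individual).
#' @return list with components \code{fec}, \code{rpa} (recruits attributed
#'   per age), \code{ns} (spawner numbers per age) and \code{rps}.
#' @examples
#' fecundityAtAge(makeStationaryFixture(), 2005)$fec  # 0 0.625 1.25
#' @export
fecundityAtAge <- function(stock, year, basis = c("perSpawner", "perCapita")) {
  basis <- match.arg(basis)
  b <- firstAge(stock)
  rps <- recruitmentRate(stock, year + 1)
  ia <- yearIndex(stock, year + 1 - b, "attribution year")
  rpa <- ssbAtAge(stock)[ia, ] * rps
  ns <- stock@Mat[ia, ] * stock@N[ia, ]
  fec <- ifelse(ns > 0, rpa / ns, 0)
  if (basis == "perCapita") fec <- fec * stock@Mat[ia, ]
  list(fec = unname(fec), rpa = unname(rpa), ns = unname(ns), rps = rps)
}

#' Mortality-at-age for one stock-year
#'
#' Fishing mortality is the annual harvest proportion catch / numbers
#' (0 where numbers are 0, flagged); total mortality is F + M; survival is
#' 1 - Z, clamped to \code{[lFloor, 1]} with a flag when Z >= 1 (the
#' proportional-rate formulation admits that pathological case).
#'
#' @param stock a [StockTable-class].
#' @param year calendar year.
#' @param lFloor positive floor for survival when Z >= 1 (default 1e-6).
#' @return list with components \code{f}, \code{z}, \code{l}, \code{flags}.
#' @examples
#' mortalityAtAge(makeStationaryFixture(), 2003)$z  # 0.2 0.5 0.5
#' @export
mortalityAtAge <- function(stock, year, lFloor = 1e-6) {
  iy <- yearIndex(stock, year)
  n <- stock@N[iy, ]
  cc <- stock@C[iy, ]
  flags <- character()
  f <- ifelse(n > 0, cc / n, 0)
  if (any(n == 0 & cc == 0))
    flags <- c(flags, sprintf("year %d: F set to 0 at ages with zero abundance", year))
  z <- f + stock@M[iy, ]
  l <- 1 - z
  if (any(l < lFloor)) {
    flags <- c(flags, sprintf("year %d: Z >= 1 at age(s) %s; survival clamped to %g",
                              year, paste(stock@ages[l < lFloor], collapse = ","),
                              lFloor))
    l <- pmax(l, lFloor)
  }
  list(f = unname(f), z = unname(z), l = pmin(unname(l), 1), flags = flags)
}

#' Cumulative survivorship-to-age
#'
#' Survivorship to the first age class is 1; each later entry multiplies the
#' previous survivorship by the previous age's survival:
#' \code{s[a] = s[a-1] * l[a-1]}. This is the within-year (period) schedule.
#'
#' @param l vector of survival-at-age values in (0, 1].
#' @return survivorship vector of the same length.
#' @examples
#' survivorshipToAge(c(0.8, 0.5, 0.5))  # 1 0.8 0.4
#' @export
survivorshipToAge <- function(l) {
  if (length(l) == 0) stop("empty survival vector", call. = FALSE)
  if (any(l <= 0) || any(l > 1))
    stop("survival values must lie in (0, 1]", call. = FALSE)
  cumprod(c(1, l[-length(l)]))
}

#' Assemble the full demographic schedule for one stock-year
#'
#' Combines [fecundityAtAge()], [mortalityAtAge()] and
#' [survivorshipToAge()] into a [LifeTable-class]: survivorship is computed
#' both under total mortality (\code{sReal}) and under natural mortality
#' only (\code{sDem}), and the age at first reproduction is the youngest age
#' with positive fecundity.
#'
#' @inheritParams fecundityAtAge
#' @param lFloor survival floor passed to [mortalityAtAge()].
#' @return a [LifeTable-class].
#' @examples
#' lt <- buildLifeTable(makeStationaryFixture(), 2004)
#' lt@sDem   # 1 0.8 0.64
#' @export
buildLifeTable <- function(stock, year, basis = c("perSpawner", "perCapita"),
                           lFloor = 1e-6) {
  basis <- match.arg(basis)
  fy <- fecundityAtAge(stock, year, basis = basis)
  mt <- mortalityAtAge(stock, year, lFloor = lFloor)
  iy <- yearIndex(stock, year)
  m <- unname(stock@M[iy, ])
  lDem <- pmax(1 - m, lFloor)
  flags <- mt$flags
  reproductive <- which(fy$fec > 0)
  nu <- if (length(reproductive)) stock@ages[min(reproductive)] else NA_integer_
  if (is.na(nu))
    flags <- c(flags, sprintf("year %d: no reproductive ages (all fecundity zero)", year))
  new("LifeTable",
      stockId = stock@stockId, year = as.integer(year), ages = stock@ages,
      rps = fy$rps, rpa = fy$rpa, ns = fy$ns, fec = fy$fec,
      f = mt$f, m = m, z = mt$z, l = mt$l,
      sReal = survivorshipToAge(mt$l), sDem = survivorshipToAge(lDem),
      nu = as.integer(nu), omega = terminalAge(stock), deltaX = 1,
      flags = flags)
}

#' Years with a complete fecundity schedule
#'
#' The fecundity of year y references recruits observed in year y + 1 and
#' spawners in year y + 1 - b, so schedules exist for years from
#' \code{firstYear + b - 1} through \code{lastYear - 1}.
#'
#' @param stock a [StockTable-class].
#' @return integer vector of calendar years.
#' @export
scheduleYears <- function(stock) {
  b <- firstAge(stock)
  yrs <- stock@years
  lo <- yrs[1] + b - 1L
  hi <- yrs[length(yrs)] - 1L
  if (lo > hi) integer(0) else seq.int(lo, hi)
}

#' Back-calculate abundance for unassessed young ages
#'
#' For stocks whose youngest assessed age b exceeds 1, extends the panel
#' down to age 1 by inverting the survival recursion along cohorts:
#' \code{N[y, a] = N[y+1, a+1] / (1 - M[y, a])}, using each year's
#' youngest-age natural mortality for the synthetic ages. Catch at
#' backfilled ages is 0, maturity 0, and weight copies the youngest assessed
#' age. Cells whose forward cohort leaves the observed span (the last b - a
#' years at synthetic age a) carry the previous year's value. Backfilled
#' ages are flagged in \code{metadata$backfilledAges}; this operation exists
#' as a sensitivity alternative to fixing first-age survivorship at 1.
#'
#' @param stock a [StockTable-class].
#' @return a [StockTable-class] extended to age 1 (the input, unchanged,
#'   when b = 1).
#' @export
backfillYoungAges <- function(stock) {
  b <- firstAge(stock)
  if (b <= 1L) {
    message("first age is already 1; nothing to backfill")
    return(stock)
  }
  ny <- length(stock@years)
  nNew <- b - 1L
  pad <- function(mat, fill) cbind(matrix(fill, ny, nNew), mat)
  N <- pad(stock@N, 0)
  for (a in nNew:1) {             # column index == age for ages 1..b-1
    for (y in seq_len(ny - 1L)) {
      N[y, a] <- N[y + 1L, a + 1L] / (1 - stock@M[y, 1])
    }
    N[ny, a] <- N[ny - 1L, a]     # forward cohort unobserved: carry previous year
  }
  StockTable(stockId = stock@stockId, species = stock@species,
             region = stock@region, years = stock@years,
             ages = seq.int(1L, terminalAge(stock)),
             N = N, C = pad(stock@C, 0),
             W = cbind(matrix(stock@W[, 1], ny, nNew), stock@W),
             Mat = pad(stock@Mat, 0),
             M = cbind(matrix(stock@M[, 1], ny, nNew), stock@M),
             metadata = c(stock@metadata,
                          list(backfilledAges = seq_len(nNew),
                               backfillNote = "ages below the assessed recruit age are synthetic back-calculations")))
}
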