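#' Calibrate one stock-year's schedule to the assessed abundance series
#'
#' Solves the Euler-Lotka equation for the year's realized lambda and, where
#' the lambda-predicted next-year total abundance (lambda * Ny) differs from
#' the assessed total (Ny+1) by more than the tolerance, iteratively adjusts
#' the year's schedules until it does not: one multiplicative step on
#' natural mortality at all ages jointly, a re-check, then (if still outside
#' tolerance) one multiplicative step on fecundity at all ages jointly, a
#' re-check, repeating. Over-prediction (lambda * Ny > Ny+1) raises M and
#' lowers fecundity; under-prediction does the opposite. Fishing mortality
#' is never adjusted. If an M step drives total mortality to 1 or beyond,
#' survival clamps at the configured floor and the fecundity steps carry the
#' remaining adjustment. Hitting \code{maxIterations} flags the year as
#' non-converged rather than raising an error.
#'
#' The fishing-excluded lambda is solved from the same adjusted natural
#' mortality and fecundity, so both rates reflect one reconstruction.
#'
#' @param stock a [StockTable-class].
#' @param year calendar year; must have a schedule (see [scheduleYears()])
#'   and a successor year with positive assessed total abundance.
#' @param cfg a [CalibrationConfig()].
#' @param basis fecundity basis passed to [buildLifeTable()].
#' @return a list with components \code{lifeTable} (the adjusted
#'   [LifeTable-class]), \code{lambdaReal}, \code{lambdaDem},
#'   \code{converged}, \code{nIterations}, \code{adjustmentM},
#'   \code{adjustmentF} and \code{predError}.
#' @examples
#' st <- makeStationaryFixture()
#' cal <- calibrateYear(st, 2004)
#' cal$lambdaReal      # 1, with zero iterations
#' cal$nIterations
#' @export
calibrateYear <- function(stock, year, cfg = CalibrationConfig(),
                          basis = c("perSpawner", "perCapita")) {
  basis <- match.arg(basis)
  iy <- yearIndex(stock, year)
  if (iy >= length(stock@years))
    stop(sprintf("year %d has no successor to calibrate against", year),
         call. = FALSE)
  tot <- totalAbundance(stock)
  ny0 <- tot[iy]
  ny1 <- tot[iy + 1L]
  if (ny1 <= 0 || ny0 <= 0)
    stop(sprintf("total abundance must be positive in years %d and %d", year,
                 year + 1), call. = FALSE)

  lt <- buildLifeTable(stock, year, basis = basis, lFloor = cfg$lFloor)
  m <- lt@m
  fec <- lt@fec
  fmort <- lt@f
  agevec <- lt@ages

  sOf <- function(m, withF) {
    z <- if (withF) fmort + m else m
    survivorshipToAge(pmin(pmax(1 - z, cfg$lFloor), 1))
  }
  lamOf <- function(m, fec) solveLambdaCore(agevec, sOf(m, TRUE), fec)

  adjM <- 1
  adjF <- 1
  iter <- 0L
  lam <- NA_real_
  err <- NA_real_
  failed <- FALSE
  tryCatch({
    lam <- lamOf(m, fec)
    err <- (lam * ny0 - ny1) / ny1
  }, error = function(e) failed <<- TRUE)

  if (!failed) {
    while (abs(err) > cfg$tolerance && iter < cfg$maxIterations) {
      # step natural mortality, re-check
      fac <- if (err > 0) 1 + cfg$step else 1 - cfg$step
      m <- m * fac
      adjM <- adjM * fac
      iter <- iter + 1L
      lam <- lamOf(m, fec)
      err <- (lam * ny0 - ny1) / ny1
      if (abs(err) <= cfg$tolerance || iter >= cfg$maxIterations) break
      # step fecundity, re-check
      fac <- if (err > 0) 1 - cfg$step else 1 + cfg$step
      fec <- fec * fac
      adjF <- adjF * fac
      iter <- iter + 1L
      lam <- lamOf(m, fec)
      err <- (lam * ny0 - ny1) / ny1
    }
  }
  converged <- !failed && is.finite(err) && abs(err) <= cfg$tolerance

  zAdj <- fmort + m
  lAdj <- pmin(pmax(1 - zAdj, cfg$lFloor), 1)
  flags <- lt@flags
  if (any(1 - zAdj < cfg$lFloor))
    flags <- c(flags, sprintf("year %d: adjusted Z >= 1; survival clamped", year))
  if (failed)
    flags <- c(flags, sprintf("year %d: no solvable reproduction; lambda undefined", year))
  reproductive <- which(fec > 0)
  ltAdj <- new("LifeTable",
               stockId = lt@stockId, year = lt@year, ages = agevec,
               rps = lt@rps, rpa = lt@rpa, ns = lt@ns, fec = fec,
               f = fmort, m = m, z = zAdj, l = lAdj,
               sReal = survivorshipToAge(lAdj),
               sDem = sOf(m, FALSE),
               nu = if (length(reproductive)) as.integer(agevec[min(reproductive)]) else NA_integer_,
               omega = lt@omega, deltaX = 1, flags = flags)

  lamDem <- if (failed) NA_real_ else
    solveLambdaCore(agevec, ltAdj@sDem, fec)
  list(lifeTable = ltAdj,
       lambdaReal = if (failed) NA_real_ else lam,
       lambdaDem = lamDem,
       converged = converged, nIterations = iter,
       adjustmentM = adjM, adjustmentF = adjF,
       predError = err)
}

#' Calibrated annual growth rates for every usable year of a stock
#'
#' Runs [calibrateYear()] for every year that has both a complete fecundity
#' schedule and a successor year; the terminal data year has no successor
#' and is excluded rather than extrapolated. Total abundance is summed over
#' ages. Years whose calibration fails (no reproduction) are kept with NA
#' rates and \code{converged = FALSE}.
#'
#' @param stock a [StockTable-class].
#' @param cfg a [CalibrationConfig()].
#' @param basis fecundity basis passed to [buildLifeTable()].
#' @return a [LambdaSeries-class].
#' @examples
#' ls <- lambdaSeries(makeStationaryFixture())
#' round(range(ls@lambdaReal), 6)   # 1 1
#' @export
lambdaSeries <- function(stock, cfg = CalibrationConfig(),
                         basis = c("perSpawner", "perCapita")) {
  basis <- match.arg(basis)
  yrs <- scheduleYears(stock)
  if (length(yrs) < 1L)
    stop(sprintf("stock '%s' has no year with both a fecundity schedule and a successor",
                 stock@stockId), call. = FALSE)
  n <- length(yrs)
  out <- new("LambdaSeries",
             stockId = stock@stockId, years = yrs,
             lambdaReal = rep(NA_real_, n), lambdaDem = rep(NA_real_, n),
             rReal = rep(NA_real_, n), rDem = rep(NA_real_, n),
             converged = rep(FALSE, n), nIterations = rep(NA_integer_, n),
             adjustmentM = rep(NA_real_, n), adjustmentF = rep(NA_real_, n),
             predError = rep(NA_real_, n), lifeTables = vector("list", n))
  for (i in seq_len(n)) {
    cal <- calibrateYear(stock, yrs[i], cfg = cfg, basis = basis)
    out@lambdaReal[i] <- cal$lambdaReal
    out@lambdaDem[i] <- cal$lambdaDem
    out@rReal[i] <- log(cal$lambdaReal)
    out@rDem[i] <- log(cal$lambdaDem)
    out@converged[i] <- cal$converged
    out@nIterations[i] <- cal$nIterations
    out@adjustmentM[i] <- cal$adjustmentM
    out@adjustmentF[i] <- cal$adjustmentF
    out@predError[i] <- cal$predError
    out@lifeTables[[i]] <- cal$lifeTable
  }
  names(out@lifeTables) <- as.character(yrs)
  if (!any(out@converged))
    stop(sprintf("calibration converged in no year of stock '%s' (years %s)",
                 stock@stockId, paste(yrs, collapse = ", ")), call. = FALSE)
  validObject(out)
  out
}
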