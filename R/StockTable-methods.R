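#' Construct a StockTable
#'
#' Assembles and validates the year-by-age panel used throughout the
#' pipeline. All five matrices must be year-major (rows are years in the
#' order of \code{years}, columns ages in the order of \code{ages}).
#'
#' @param stockId,species,region single character labels.
#' @param years integer vector of consecutive calendar years.
#' @param ages integer vector of consecutive ages (recruit age to terminal age).
#' @param N,C,W,Mat,M numbers-at-age, catch-numbers-at-age, weight-at-age (kg),
#'   maturity-proportion and natural-mortality-proportion matrices.
#' @param metadata optional list of annotations.
#' @return a validated [StockTable-class] object.
#' @examples
#' st <- makeStationaryFixture()
#' totalAbundance(st)
#' @export
StockTable <- function(stockId, species = "unknown", region = "unknown",
                       years, ages, N, C, W, Mat, M, metadata = list()) {
  dm <- list(as.character(years), as.character(ages))
  fix <- function(x) {
    x <- as.matrix(x)
    dimnames(x) <- dm
    x
  }
  # slots assigned individually: the slot named 'C' would otherwise be
  # partially matched to new()'s 'Class' argument
  obj <- new("StockTable")
  obj@stockId <- as.character(stockId)
  obj@species <- as.character(species)
  obj@region <- as.character(region)
  obj@years <- as.integer(years)
  obj@ages <- as.integer(ages)
  obj@N <- fix(N)
  obj@C <- fix(C)
  obj@W <- fix(W)
  obj@Mat <- fix(Mat)
  obj@M <- fix(M)
  obj@metadata <- metadata
  validObject(obj)
  obj
}

#' @rdname StockTable-accessors
#' @export
setGeneric("stockId", function(object) standardGeneric("stockId"))

#' Accessors for StockTable slots
#'
#' \code{stockId}, \code{years}, \code{ages} return the identifying vectors;
#' \code{abundance}, \code{catchN}, \code{weightAtAge}, \code{maturity},
#' \code{natMortality} return the year-by-age matrices; \code{firstAge} is
#' the recruit age b and \code{terminalAge} the terminal age omega.
#'
#' @param object a [StockTable-class].
#' @return vectors or year-by-age matrices as described.
#' @name StockTable-accessors
NULL

#' @rdname StockTable-accessors
#' @export
setMethod("stockId", "StockTable", function(object) object@stockId)

#' @rdname StockTable-accessors
#' @export
setGeneric("years", function(object) standardGeneric("years"))
#' @rdname StockTable-accessors
#' @export
setMethod("years", "StockTable", function(object) object@years)

#' @rdname StockTable-accessors
#' @export
setGeneric("ages", function(object) standardGeneric("ages"))
#' @rdname StockTable-accessors
#' @export
setMethod("ages", "StockTable", function(object) object@ages)

#' @rdname StockTable-accessors
#' @export
setGeneric("abundance", function(object) standardGeneric("abundance"))
#' @rdname StockTable-accessors
#' @export
setMethod("abundance", "StockTable", function(object) object@N)

#' @rdname StockTable-accessors
#' @export
setGeneric("catchN", function(object) standardGeneric("catchN"))
#' @rdname StockTable-accessors
#' @export
setMethod("catchN", "StockTable", function(object) object@C)

#' @rdname StockTable-accessors
#' @export
setGeneric("weightAtAge", function(object) standardGeneric("weightAtAge"))
#' @rdname StockTable-accessors
#' @export
setMethod("weightAtAge", "StockTable", function(object) object@W)

#' @rdname StockTable-accessors
#' @export
setGeneric("maturity", function(object) standardGeneric("maturity"))
#' @rdname StockTable-accessors
#' @export
setMethod("maturity", "StockTable", function(object) object@Mat)

#' @rdname StockTable-accessors
#' @export
setGeneric("natMortality", function(object) standardGeneric("natMortality"))
#' @rdname StockTable-accessors
#' @export
setMethod("natMortality", "StockTable", function(object) object@M)

#' @rdname StockTable-accessors
#' @export
firstAge <- function(object) object@ages[1]

#' @rdname StockTable-accessors
#' @export
terminalAge <- function(object) object@ages[length(object@ages)]

#' Total abundance and spawning stock biomass by year
#'
#' \code{totalAbundance} sums numbers over ages for each year;
#' \code{ssb} sums weight x maturity x numbers (kg) and \code{ssbAtAge}
#' returns the same product disaggregated by age.
#'
#' @param object a [StockTable-class].
#' @return a named numeric vector by year (\code{totalAbundance}, \code{ssb})
#'   or a year-by-age matrix (\code{ssbAtAge}).
#' @examples
#' ssb(makeStationaryFixture())
#' @export
setGeneric("totalAbundance", function(object) standardGeneric("totalAbundance"))

#' @rdname totalAbundance
#' @export
setMethod("totalAbundance", "StockTable",
          function(object) rowSums(object@N))

#' @rdname totalAbundance
#' @export
setGeneric("ssb", function(object) standardGeneric("ssb"))
#' @rdname totalAbundance
#' @export
setMethod("ssb", "StockTable", function(object) rowSums(ssbAtAge(object)))

#' @rdname totalAbundance
#' @export
ssbAtAge <- function(object) object@W * object@Mat * object@N

yearIndex <- function(stock, year, what = "year") {
  i <- match(as.integer(year), stock@years)
  if (is.na(i))
    stop(sprintf("%s %s is outside the observed span %d-%d of stock '%s'",
                 what, year, stock@years[1],
                 stock@years[length(stock@years)], stock@stockId),
         call. = FALSE)
  i
}

setMethod("show", "StockTable", function(object) {
  cat(sprintf("StockTable '%s' (%s, %s)\n", object@stockId, object@species,
              object@region))
  cat(sprintf("  years: %d-%d (%d), ages: %d-%d\n",
              object@years[1], object@years[length(object@years)],
              length(object@years), object@ages[1],
              object@ages[length(object@ages)]))
  tot <- totalAbundance(object)
  cat(sprintf("  total abundance: %.4g .. %.4g (max %.4g)\n",
              tot[1], tot[length(tot)], max(tot)))
})

#' Coerce pipeline objects to data.frame
#'
#' \code{StockTable} becomes the long format used for CSV interchange
#' (one row per year-age); \code{LifeTable} one row per age;
#' \code{LambdaSeries} and \code{RecoveryResult} one row per year.
#'
#' @param x object to coerce.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return a data.frame.
#' @export
as.data.frame.StockTable <- function(x, row.names = NULL, optional = FALSE, ...) {
  grid <- expand.grid(year = x@years, age = x@ages, KEEP.OUT.ATTRS = FALSE)
  data.frame(
    stock_id = x@stockId, species = x@species, region = x@region,
    year = grid$year, age = grid$age,
    abundance_n = as.vector(x@N), catch_n = as.vector(x@C),
    weight_kg = as.vector(x@W), maturity_prop = as.vector(x@Mat),
    m_annual = as.vector(x@M),
    stringsAsFactors = FALSE)
}

setMethod("show", "LifeTable", function(object) {
  cat(sprintf("LifeTable %s year %d (ages %d-%d)\n", object@stockId,
              object@year, object@ages[1], object@omega))
  cat(sprintf("  nu = %s, RPS = %.4g recruits/kg\n",
              ifelse(is.na(object@nu), "NA", object@nu), object@rps))
  print(round(data.frame(age = object@ages, fec = object@fec, F = object@f,
                         M = object@m, Z = object@z, l = object@l,
                         s_real = object@sReal, s_dem = object@sDem), 4),
        row.names = FALSE)
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

#' @rdname as.data.frame.StockTable
#' @export
as.data.frame.LifeTable <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(stock_id = x@stockId, year = x@year, age = x@ages,
             rps = x@rps, rpa = x@rpa, ns = x@ns, fec = x@fec,
             f_mort = x@f, m_nat = x@m, z = x@z, l = x@l,
             s_real = x@sReal, s_dem = x@sDem, stringsAsFactors = FALSE)
}

setMethod("show", "LambdaSeries", function(object) {
  cat(sprintf("LambdaSeries '%s': %d years (%d-%d), %d converged\n",
              object@stockId, length(object@years),
              min(object@years), max(object@years), sum(object@converged)))
  ok <- !is.na(object@lambdaReal)
  if (any(ok))
    cat(sprintf("  median lambda_real %.3f, median lambda_dem %.3f\n",
                stats::median(object@lambdaReal[ok]),
                stats::median(object@lambdaDem[ok])))
})

#' @rdname as.data.frame.StockTable
#' @export
as.data.frame.LambdaSeries <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(stock_id = x@stockId, year = x@years,
             lambda_real = x@lambdaReal, lambda_dem = x@lambdaDem,
             r_real = x@rReal, r_dem = x@rDem,
             converged = x@converged, n_iterations = x@nIterations,
             adjustment_m = x@adjustmentM, adjustment_f = x@adjustmentF,
             pred_error = x@predError, stringsAsFactors = FALSE)
}

setMethod("show", "CohortRecord", function(object) {
  cat(sprintf("CohortRecord '%s' cohort %d (ages %d-%d)%s\n",
              object@stockId, object@cohortYear, object@ages[1],
              object@ages[length(object@ages)],
              if (object@fullSchedules) "" else " [partial schedules]"))
  cat(sprintf("  R0 with F = %.4g, R0 no F = %.4g; LG with F = %.4g, LG no F = %.4g\n",
              object@r0WithF, object@r0NoF, object@lgWithF, object@lgNoF))
})

setMethod("show", "DDFit", function(object) {
  cat(sprintf("DDFit (basis '%s'): %d observations, %d stocks\n",
              object@basis, nrow(object@data),
              length(unique(object@data$stock_id))))
})

setMethod("show", "RecoveryResult", function(object) {
  i10 <- match(10L, object@years)
  i20 <- match(20L, object@years)
  cat(sprintf("RecoveryResult '%s': %s recovery potential\n",
              object@stockId, object@classification))
  cat(sprintf("  doubled by year 10: %.1f%%, by year 20: %.1f%%\n",
              100 * object@propDoubled[i10], 100 * object@propDoubled[i20]))
})

#' @rdname as.data.frame.StockTable
#' @export
as.data.frame.RecoveryResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(stock_id = x@stockId, year = x@years,
             prop_doubled = x@propDoubled, stringsAsFactors = FALSE)
}
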