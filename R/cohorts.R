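#' Extract complete cohorts from calibrated per-year schedules
#'
#' A cohort is identified by the calendar year in which it appears at the
#' recruit age b; it is complete when every age b..omega falls inside the
#' observed span, i.e. cohorts starting in the first \code{nYears - (omega -
#' b)} years. Cohort schedules are read along the diagonal of the calibrated
#' per-year life tables (year c + x - b, age x), so survival and fecundity
#' reflect the same adjusted rates as the lambda series. The terminal data
#' year has no fecundity schedule, so the youngest complete cohort carries
#' an NA fecundity at its final age and its R0 and generation length are NA
#' (\code{fullSchedules = FALSE}); its survivorship, which only needs
#' survival up to age omega - 1, is still computed.
#'
#' @param stock a [StockTable-class].
#' @param series the [LambdaSeries-class] for the same stock, carrying the
#'   calibrated life tables. Pass the result of [lambdaSeries()] run with
#'   calibration disabled-in-effect (a huge tolerance) to study uncalibrated
#'   schedules.
#' @return a list of [CohortRecord-class] objects (empty, with a message,
#'   when the span is too short for any complete cohort).
#' @examples
#' st <- makeStationaryFixture()
#' cohorts <- extractCompleteCohorts(st, lambdaSeries(st))
#' length(cohorts)   # 8 complete cohorts from 10 years of ages 1-3
#' @export
extractCompleteCohorts <- function(stock, series) {
  if (!identical(series@stockId, stock@stockId))
    warning("stock and series labels differ; pairing them anyway")
  b <- firstAge(stock)
  omega <- terminalAge(stock)
  agevec <- stock@ages
  k <- length(agevec)
  yrs <- stock@years
  starts <- yrs[seq_len(max(0L, length(yrs) - (omega - b)))]
  if (length(starts) == 0L) {
    message(sprintf("stock '%s': span too short for any complete cohort",
                    stock@stockId))
    return(list())
  }
  lapply(starts, function(cy) {
    schedYears <- cy + agevec - b
    lts <- series@lifeTables[as.character(schedYears)]
    lWithF <- lNoF <- fec <- rep(NA_real_, k)
    for (i in seq_len(k)) {
      lt <- lts[[i]]
      if (!is.null(lt)) {
        lWithF[i] <- lt@l[i]
        lNoF[i] <- max(1 - lt@m[i], 1e-6)
        fec[i] <- lt@fec[i]
      } else {
        # no calibrated schedule (terminal data year): survival from the raw
        # panel so survivorship stays defined; fecundity is unknowable
        mt <- mortalityAtAge(stock, schedYears[i])
        lWithF[i] <- mt$l[i]
        lNoF[i] <- max(1 - stock@M[yearIndex(stock, schedYears[i]), i], 1e-6)
      }
    }
    sWithF <- cumprod(c(1, lWithF[-k]))
    sNoF <- cumprod(c(1, lNoF[-k]))
    full <- !anyNA(fec)
    rec <- new("CohortRecord",
               stockId = stock@stockId, cohortYear = as.integer(cy),
               ages = agevec, sWithF = sWithF, sNoF = sNoF, fec = fec,
               r0WithF = NA_real_, r0NoF = NA_real_,
               lgWithF = NA_real_, lgNoF = NA_real_,
               complete = TRUE, fullSchedules = full)
    if (full) {
      rec@r0WithF <- lifetimeReproductiveSuccess(rec, includeFishing = TRUE)
      rec@r0NoF <- lifetimeReproductiveSuccess(rec, includeFishing = FALSE)
      if (rec@r0WithF > 0) {
        rec@lgWithF <- generationLength(rec, includeFishing = TRUE)
        rec@lgNoF <- generationLength(rec, includeFishing = FALSE)
      }
    }
    rec
  })
}

#' Lifetime reproductive success of a cohort
#'
#' The survivorship-weighted sum of cohort fecundity,
#' \eqn{R_0 = \sum_{x=\alpha}^{\omega} s_x f_x}: the expected number of
#' spawners produced per spawner over a lifetime, with 1 marking
#' replacement. Under the assumed 50:50 sex ratio the per-spawner units
#' cancel, so no additional factor of one half is applied: one recruit per
#' spawner is one female recruit per female spawner. The sum stops at the
#' terminal age (no plus-group contribution). The fishing-excluded variant
#' replaces survivorship with the natural-mortality-only schedule but keeps
#' the observed fecundities, so it removes direct fishing deaths without
#' undoing fishing's imprint on the observed age structure.
#'
#' @param cohort a [CohortRecord-class] with \code{complete = TRUE} and full
#'   schedules.
#' @param includeFishing use survivorship under F + M (TRUE) or M only.
#' @return spawners per spawner (scalar).
#' @examples
#' st <- makeStationaryFixture()
#' coh <- extractCompleteCohorts(st, lambdaSeries(st))[[1]]
#' lifetimeReproductiveSuccess(coh)                          # 1
#' lifetimeReproductiveSuccess(coh, includeFishing = FALSE)  # 1.3
#' @export
lifetimeReproductiveSuccess <- function(cohort, includeFishing = TRUE) {
  if (!cohort@complete)
    stop("cohort is incomplete; R0 is undefined", call. = FALSE)
  if (anyNA(cohort@fec))
    stop("cohort lacks a fecundity schedule at some age; R0 is undefined",
         call. = FALSE)
  s <- if (includeFishing) cohort@sWithF else cohort@sNoF
  sum(s * cohort@fec)
}

#' Generation length of a cohort
#'
#' The mean age of the spawners that produced the cohort's recruits,
#' \eqn{L_G = \sum x s_x f_x / \sum s_x f_x}. Fishing truncates the age
#' structure, so the fishing-inclusive generation length is at most the
#' fishing-excluded one.
#'
#' @inheritParams lifetimeReproductiveSuccess
#' @return years (scalar).
#' @examples
#' st <- makeStationaryFixture()
#' coh <- extractCompleteCohorts(st, lambdaSeries(st))[[1]]
#' generationLength(coh)                           # 2.5
#' generationLength(coh, includeFishing = FALSE)   # about 2.615
#' @export
generationLength <- function(cohort, includeFishing = TRUE) {
  if (!cohort@complete)
    stop("cohort is incomplete; generation length is undefined", call. = FALSE)
  if (anyNA(cohort@fec))
    stop("cohort lacks a fecundity schedule at some age", call. = FALSE)
  s <- if (includeFishing) cohort@sWithF else cohort@sNoF
  w <- s * cohort@fec
  tot <- sum(w)
  if (tot <= 0)
    stop("cohort has zero lifetime reproduction; generation length undefined",
         call. = FALSE)
  sum(cohort@ages * w) / tot
}

#' Tabulate cohort metrics
#'
#' One row per cohort: R0 and generation length with and without fishing.
#'
#' @param cohorts list of [CohortRecord-class] from [extractCompleteCohorts()].
#' @return a data.frame with columns stock_id, cohort_year, r0_f, r0_nof,
#'   lg_f, lg_nof, complete, full_schedules.
#' @export
cohortSummary <- function(cohorts) {
  if (length(cohorts) == 0L)
    return(data.frame(stock_id = character(), cohort_year = integer(),
                      r0_f = numeric(), r0_nof = numeric(),
                      lg_f = numeric(), lg_nof = numeric(),
                      complete = logical(), full_schedules = logical()))
  do.call(rbind, lapply(cohorts, function(x)
    data.frame(stock_id = x@stockId, cohort_year = x@cohortYear,
               r0_f = x@r0WithF, r0_nof = x@r0NoF,
               lg_f = x@lgWithF, lg_nof = x@lgNoF,
               complete = x@complete, full_schedules = x@fullSchedules,
               stringsAsFactors = FALSE)))
}
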