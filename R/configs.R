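#' Simulation configuration for the age-structured stock generator
#'
#' Defines the conditions under which [generateStock()] forward-simulates an
#' assessment-like panel: an age-truncated cohort model with proportional
#' survival, recruitment proportional to spawning biomass with mean-corrected
#' lognormal variability, and an independent Bernoulli "large event"
#' multiplier emulating the infrequent strong year classes of marine
#' teleosts.
#'
#' The defaults describe a moderately long-lived demersal stock: ages 1-10
#' (no plus group), constant natural mortality 0.2, logistic maturity
#' centred on age 3, von-Bertalanffy-type weight growth to about 4.3 kg,
#' logistic fishery selectivity rising to an annual harvest proportion of
#' 0.35, recruitment CV 0.6 with an 8-fold large event at probability 0.1
#' per year, and a 40-year series. The mean recruitment rate (0.4 recruits
#' per kg of spawning biomass) sits just above replacement under that
#' fishing pressure, so simulated stocks fluctuate around a slowly drifting
#' abundance rather than trending deterministically.
#'
#' @param nYears number of simulated calendar years.
#' @param firstAge recruit age b (the youngest assessed age).
#' @param maxAge terminal age omega; ages run b..omega with no plus group.
#' @param recruitsPerKgMean mean recruits produced per kg of spawning biomass.
#' @param recruitmentCv coefficient of variation of the lognormal recruitment
#'   deviate (mean-corrected so the expectation is 1).
#' @param largeEventProb per-year probability of a large recruitment event.
#' @param largeEventMultiplier multiplier (>= 1) applied in large-event years.
#' @param mAtAge annual natural mortality proportion, one value per age (a
#'   scalar is recycled).
#' @param fSelectivity annual fishing mortality proportion per age; must
#'   satisfy mAtAge + fSelectivity < 1.
#' @param weightAtAge mean weight (kg) per age, positive.
#' @param maturityAtAge maturity proportion per age, in [0, 1].
#' @param initialAbundance numbers at the recruit age in the first year.
#' @param seed integer seed making the simulation reproducible.
#' @return a validated list of class \code{"SimConfig"}.
#' @examples
#' cfg <- SimConfig(nYears = 20, seed = 7)
#' st <- generateStock(cfg)
#' @export
SimConfig <- function(nYears = 40L,
                      firstAge = 1L,
                      maxAge = 10L,
                      recruitsPerKgMean = 0.4,
                      recruitmentCv = 0.6,
                      largeEventProb = 0.1,
                      largeEventMultiplier = 8,
                      mAtAge = 0.2,
                      fSelectivity = NULL,
                      weightAtAge = NULL,
                      maturityAtAge = NULL,
                      initialAbundance = 1e6,
                      seed = 1L) {
  firstAge <- as.integer(firstAge)
  maxAge <- as.integer(maxAge)
  agevec <- seq.int(firstAge, maxAge)
  k <- length(agevec)
  if (is.null(fSelectivity)) fSelectivity <- 0.35 / (1 + exp(-2 * (agevec - 4)))
  if (is.null(weightAtAge)) weightAtAge <- 5 * (1 - exp(-0.3 * agevec))^3
  if (is.null(maturityAtAge)) maturityAtAge <- 1 / (1 + exp(-2 * (agevec - 3)))
  if (length(mAtAge) == 1L) mAtAge <- rep(mAtAge, k)
  cfg <- structure(list(
    nYears = as.integer(nYears), firstAge = firstAge, maxAge = maxAge,
    recruitsPerKgMean = recruitsPerKgMean, recruitmentCv = recruitmentCv,
    largeEventProb = largeEventProb,
    largeEventMultiplier = largeEventMultiplier,
    mAtAge = as.numeric(mAtAge), fSelectivity = as.numeric(fSelectivity),
    weightAtAge = as.numeric(weightAtAge),
    maturityAtAge = as.numeric(maturityAtAge),
    initialAbundance = initialAbundance, seed = as.integer(seed)),
    class = "SimConfig")
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  k <- cfg$maxAge - cfg$firstAge + 1L
  if (cfg$nYears < 2L) stop("nYears must be at least 2", call. = FALSE)
  if (k < 1L) stop("maxAge must be >= firstAge", call. = FALSE)
  for (nm in c("mAtAge", "fSelectivity", "weightAtAge", "maturityAtAge"))
    if (length(cfg[[nm]]) != k)
      stop(sprintf("'%s' must have %d entries (one per age %d..%d)",
                   nm, k, cfg$firstAge, cfg$maxAge), call. = FALSE)
  if (any(cfg$mAtAge < 0) || any(cfg$mAtAge >= 1))
    stop("mAtAge must lie in [0, 1)", call. = FALSE)
  if (any(cfg$fSelectivity < 0) || any(cfg$fSelectivity >= 1))
    stop("fSelectivity must lie in [0, 1)", call. = FALSE)
  if (any(cfg$mAtAge + cfg$fSelectivity >= 1))
    stop("mAtAge + fSelectivity must be < 1 at every age", call. = FALSE)
  if (any(cfg$weightAtAge <= 0)) stop("weightAtAge must be positive", call. = FALSE)
  if (any(cfg$maturityAtAge < 0) || any(cfg$maturityAtAge > 1))
    stop("maturityAtAge must lie in [0, 1]", call. = FALSE)
  if (cfg$largeEventProb < 0 || cfg$largeEventProb > 1)
    stop("largeEventProb must lie in [0, 1]", call. = FALSE)
  if (cfg$largeEventMultiplier < 1)
    stop("largeEventMultiplier must be >= 1", call. = FALSE)
  if (cfg$recruitmentCv < 0) stop("recruitmentCv must be >= 0", call. = FALSE)
  if (cfg$recruitsPerKgMean <= 0)
    stop("recruitsPerKgMean must be positive", call. = FALSE)
  if (cfg$initialAbundance <= 0)
    stop("initialAbundance must be positive", call. = FALSE)
  invisible(cfg)
}

#' Calibration settings for the abundance-matching lambda estimation
#'
#' Controls the iterative minimization that adjusts each year's natural
#' mortality and fecundity schedules until the Euler-Lotka lambda predicts
#' next-year abundance within \code{tolerance} of the assessed series.
#' Each accepted step multiplies a whole schedule by (1 +/- \code{step});
#' natural mortality is stepped first, fecundity second, alternating.
#'
#' @param tolerance relative tolerance on |lambda * Ny - Ny+1| / Ny+1
#'   (default 0.05, i.e. 5%).
#' @param step relative step size per adjustment (default 0.005, i.e. 0.5%;
#'   0.0005 is a useful fallback for stocks needing finer steps).
#' @param maxIterations cap on total adjustment steps per year.
#' @param lFloor floor for survival-at-age when Z >= 1.
#' @return a validated list of class \code{"CalibrationConfig"}.
#' @export
CalibrationConfig <- function(tolerance = 0.05, step = 0.005,
                              maxIterations = 1e5, lFloor = 1e-6) {
  if (!(step > 0 && tolerance > step && tolerance < 1))
    stop("need 0 < step < tolerance < 1", call. = FALSE)
  if (maxIterations < 1) stop("maxIterations must be >= 1", call. = FALSE)
  structure(list(tolerance = tolerance, step = step,
                 maxIterations = as.integer(maxIterations), lFloor = lFloor),
            class = "CalibrationConfig")
}

#' Settings for the Monte Carlo doubling-time projection
#'
#' @param nSims number of simulated trajectories (default 1000).
#' @param horizon projection length in years (default 100; must cover the
#'   year-20 classification check).
#' @param seed integer seed for the resampling.
#' @param highThreshold proportion doubled by year 10 needed for "high"
#'   recovery potential (default 0.75).
#' @param moderateThreshold proportion doubled by year 20 needed for
#'   "moderate" (default 0.50).
#' @return a validated list of class \code{"RecoveryConfig"}.
#' @export
RecoveryConfig <- function(nSims = 1000L, horizon = 100L, seed = 1L,
                           highThreshold = 0.75, moderateThreshold = 0.50) {
  if (nSims < 1) stop("nSims must be >= 1", call. = FALSE)
  if (horizon < 20) stop("horizon must be >= 20", call. = FALSE)
  if (highThreshold <= 0 || highThreshold > 1 ||
      moderateThreshold <= 0 || moderateThreshold > 1)
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  structure(list(nSims = as.integer(nSims), horizon = as.integer(horizon),
                 seed = as.integer(seed), highThreshold = highThreshold,
                 moderateThreshold = moderateThreshold),
            class = "RecoveryConfig")
}
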