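#' Monte Carlo doubling-time projection in the absence of fishing
#'
#' For each simulated trajectory and projection year, one observed year's
#' fecundity-at-age vector and - independently - one observed year's natural
#' mortality-at-age vector are drawn uniformly with replacement from the
#' calibrated reconstruction (no correlation between fecundity and natural
#' mortality is imposed). The F = 0 life table for the drawn pair is built,
#' the Euler-Lotka equation solved for lambda, and relative abundance
#' (starting at 1) multiplied by it. Doubling is absorbing: once a
#' trajectory reaches twice its initial abundance it is considered to have
#' stayed there, so the proportion-doubled curve is nondecreasing and
#' reflects the earliest possible doubling time. No density dependence is
#' applied. Results are deterministic given \code{cfg$seed}; only abundance
#' ratios matter, so the result is invariant to units.
#'
#' Lambda is precomputed for every (mortality-year, fecundity-year) pair, so
#' the cost is one root solve per pair rather than per trajectory-year.
#' A drawn pair with zero reproduction contributes a collapse-level lambda
#' (the trajectory continues, far below doubling); if every pair has zero
#' reproduction the curve is identically 0.
#'
#' @param rates a [LambdaSeries-class] (its calibrated life tables supply
#'   the annual fecundity and natural-mortality schedules), or a list with
#'   matrices \code{fec} and \code{m} (years x ages) plus \code{ages}.
#' @param cfg a [RecoveryConfig()].
#' @param stockId label for the result (defaults to the series' stock).
#' @return a [RecoveryResult-class].
#' @examples
#' st <- makeStationaryFixture()
#' res <- projectDoubling(lambdaSeries(st), RecoveryConfig(nSims = 200, seed = 1))
#' res@propDoubled[7]   # 1: doubles in year 7 on every trajectory
#' @export
projectDoubling <- function(rates, cfg = RecoveryConfig(), stockId = NULL) {
  if (is(rates, "LambdaSeries")) {
    lts <- rates@lifeTables
    if (length(lts) == 0L) stop("series carries no life tables", call. = FALSE)
    agevec <- lts[[1]]@ages
    fec <- do.call(rbind, lapply(lts, slot, "fec"))
    m <- do.call(rbind, lapply(lts, slot, "m"))
    if (is.null(stockId)) stockId <- rates@stockId
  } else {
    fec <- rates$fec
    m <- rates$m
    agevec <- rates$ages
    if (is.null(stockId)) stockId <- "stock"
  }
  nyr <- nrow(fec)
  if (nyr < 1L) stop("need at least one year of calibrated rates", call. = FALSE)

  # lambda for every (m-year, fecundity-year) pair; zero reproduction -> ~0
  logLam <- matrix(NA_real_, nyr, nyr)
  for (im in seq_len(nyr)) {
    s <- survivorshipToAge(pmin(pmax(1 - m[im, ], 1e-6), 1))
    for (jf in seq_len(nyr)) {
      lam <- tryCatch(solveLambdaCore(agevec, s, fec[jf, ]),
                      error = function(e) 1e-12)
      logLam[im, jf] <- log(lam)
    }
  }

  set.seed(cfg$seed)
  h <- cfg$horizon
  ns <- cfg$nSims
  imat <- matrix(sample.int(nyr, h * ns, replace = TRUE), h, ns)
  jmat <- matrix(sample.int(nyr, h * ns, replace = TRUE), h, ns)
  steps <- matrix(logLam[cbind(as.vector(imat), as.vector(jmat))], h, ns)
  logAbund <- apply(steps, 2, cumsum)
  if (h == 1L) logAbund <- matrix(logAbund, 1L, ns)
  doubledBy <- logAbund >= log(2)
  firstDoubling <- apply(doubledBy, 2, function(x) {
    w <- which(x)
    if (length(w)) w[1] else NA_real_
  })
  propDoubled <- vapply(seq_len(h), function(t)
    mean(!is.na(firstDoubling) & firstDoubling <= t), numeric(1))

  res <- new("RecoveryResult", stockId = as.character(stockId),
             years = seq_len(h), propDoubled = propDoubled,
             firstDoubling = firstDoubling,
             classification = "unclassified")
  res@classification <- classifyRecovery(res, cfg)
  validObject(res)
  res
}

#' Three-way recovery-potential classification
#'
#' "high" when at least 75% of trajectories have doubled by projection year
#' 10; otherwise "moderate" when at least 50% have doubled by year 20;
#' otherwise "low". A stock that reaches 75% doubled only by year 20 is
#' moderate: the high class is defined strictly at year 10.
#'
#' @param res a [RecoveryResult-class] whose curve covers years 10 and 20.
#' @param cfg a [RecoveryConfig()] supplying the thresholds.
#' @return "high", "moderate" or "low".
#' @export
classifyRecovery <- function(res, cfg = RecoveryConfig()) {
  i10 <- match(10L, res@years)
  i20 <- match(20L, res@years)
  if (is.na(i10) || is.na(i20))
    stop("propDoubled must cover projection years 10 and 20", call. = FALSE)
  if (res@propDoubled[i10] >= cfg$highThreshold) "high"
  else if (res@propDoubled[i20] >= cfg$moderateThreshold) "moderate"
  else "low"
}
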