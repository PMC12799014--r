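#' Relative abundance: proportion of the maximum observed total
#'
#' Each year's total abundance (summed over ages) divided by the maximum
#' total over the observed span; the maximum year has proportion 1.
#'
#' @param stock a [StockTable-class].
#' @return named numeric vector of proportions in (0, 1], one per year.
#' @examples
#' abundanceProportion(makeGeometricFixture(2, nYears = 3))  # 0.25 0.5 1
#' @export
abundanceProportion <- function(stock) {
  tot <- totalAbundance(stock)
  mx <- max(tot)
  if (mx <= 0)
    stop(sprintf("stock '%s' has zero abundance in every year", stock@stockId),
         call. = FALSE)
  tot / mx
}

#' Assemble density-dependence observations from calibrated series
#'
#' Pairs each stock-year's calibrated lambda with that year's proportion of
#' maximum abundance.
#'
#' @param stocks list of [StockTable-class] objects.
#' @param seriesList list of matching [LambdaSeries-class] objects.
#' @param basis which rate to model: \code{"real"} (fishing included) or
#'   \code{"dem"} (fishing excluded).
#' @param convergedOnly drop non-converged years (default TRUE).
#' @return a data.frame with columns stock_id, year, prop, lam.
#' @export
ddObservations <- function(stocks, seriesList, basis = c("real", "dem"),
                           convergedOnly = TRUE) {
  basis <- match.arg(basis)
  stopifnot(length(stocks) == length(seriesList))
  out <- mapply(function(st, se) {
    props <- abundanceProportion(st)
    lam <- if (basis == "real") se@lambdaReal else se@lambdaDem
    keep <- if (convergedOnly) se@converged & !is.na(lam) else !is.na(lam)
    data.frame(stock_id = se@stockId, year = se@years[keep],
               prop = unname(props[match(se@years[keep], st@years)]),
               lam = lam[keep], stringsAsFactors = FALSE)
  }, stocks, seriesList, SIMPLIFY = FALSE)
  do.call(rbind, out)
}

#' Fit the hierarchical smooth of lambda against relative abundance
#'
#' Models log(lambda) as a global penalized cubic spline of the proportion
#' of maximum abundance plus per-stock factor-smooth deviations that share a
#' single smoothing penalty (random-effect smooths, \code{bs = "fs"} in
#' \pkg{mgcv}), with Gaussian errors on the log scale. Fitting log(lambda)
#' with Gaussian errors is operationally equivalent to a lognormal response
#' and numerically stabler. The fit is deterministic given the data. The
#' model is used descriptively - to extract a global curve and per-stock
#' anchor values - not for formal inference on the smooths.
#'
#' @param obs data.frame from [ddObservations()] (columns stock_id, prop,
#'   lam; prop in (0, 1], lam > 0).
#' @param basis label recorded in the result ("real" or "dem").
#' @param k basis dimension of the global smooth (default 10).
#' @param kStock basis dimension of each per-stock smooth (default 5).
#' @return a [DDFit-class].
#' @examples
#' \donttest{
#' stocks <- lapply(1:4, function(i) generateStock(SimConfig(nYears = 25,
#'   seed = i), stockId = paste0("s", i)))
#' series <- lapply(stocks, lambdaSeries)
#' fit <- fitDensityDependence(ddObservations(stocks, series, "real"))
#' lambdaAtAnchors(fit, "s1")
#' }
#' @export
fitDensityDependence <- function(obs, basis = c("real", "dem"), k = 10,
                                 kStock = 5) {
  basis <- match.arg(basis)
  need <- c("stock_id", "prop", "lam")
  if (!all(need %in% names(obs)))
    stop("obs must have columns stock_id, prop, lam", call. = FALSE)
  if (any(!is.finite(obs$lam)) || any(obs$lam <= 0))
    stop("lambda values must be positive and finite", call. = FALSE)
  if (any(obs$prop <= 0) || any(obs$prop > 1))
    stop("prop must lie in (0, 1]", call. = FALSE)
  nStocks <- length(unique(obs$stock_id))
  if (nStocks < 2)
    stop("need at least 2 stocks to fit per-stock smooths", call. = FALSE)
  perStock <- table(obs$stock_id)
  if (any(perStock < 10))
    warning(sprintf("%d stock(s) have fewer than 10 observations; per-stock smooths may be weakly identified",
                    sum(perStock < 10)))
  dat <- data.frame(loglam = log(obs$lam), prop = obs$prop,
                    stock = factor(obs$stock_id))
  kStock <- min(kStock, max(3, floor(nrow(dat) / nStocks)))
  form <- loglam ~ s(prop, k = k, bs = "cr") + s(prop, stock, bs = "fs", k = kStock)
  # mgcv flags the global smooth and the factor-smooth deviations as repeated
  # 1-d smooths of prop; the shared-penalty setup is intentional, so that
  # specific warning is muffled while anything else propagates
  quietGam <- function(...) withCallingHandlers(
    mgcv::gam(...),
    warning = function(w) {
      if (grepl("repeated 1-d smooths", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  model <- tryCatch(
    quietGam(form, data = dat, method = "REML"),
    error = function(e) {
      # degenerate data (e.g. a constant response) can break REML smoothing-
      # parameter estimation; refit with heavy fixed penalties, which shrinks
      # every smooth towards the parametric fit
      skeleton <- quietGam(form, data = dat, fit = FALSE)
      quietGam(form, data = dat, sp = rep(1e5, length(skeleton$sp)))
    })
  minProp <- tapply(obs$prop, obs$stock_id, min)
  new("DDFit", basis = basis, model = model, data = obs,
      minProp = stats::setNames(as.numeric(minProp), names(minProp)))
}

#' Evaluate the global density-dependence curve
#'
#' The population-level smooth (per-stock deviations excluded) with a
#' pointwise 95% interval, back-transformed to the lambda scale.
#'
#' @param fit a [DDFit-class].
#' @param props proportions of maximum abundance at which to evaluate.
#' @return data.frame with columns prop, lambda, lower, upper.
#' @export
globalCurve <- function(fit, props = seq(0.05, 1, by = 0.05)) {
  levs <- levels(fit@model$model$stock)
  nd <- data.frame(prop = props, stock = factor(levs[1], levels = levs))
  pr <- mgcv::predict.gam(fit@model, newdata = nd, se.fit = TRUE,
                          exclude = "s(prop,stock)")
  data.frame(prop = props, lambda = exp(as.numeric(pr$fit)),
             lower = exp(as.numeric(pr$fit - 1.96 * pr$se.fit)),
             upper = exp(as.numeric(pr$fit + 1.96 * pr$se.fit)))
}

#' Evaluate one stock's fitted curve
#'
#' The full prediction (global smooth plus the stock's deviation smooth) on
#' the lambda scale.
#'
#' @inheritParams globalCurve
#' @param stockIdValue stock label present in the fit.
#' @return data.frame with columns prop, lambda.
#' @export
stockCurve <- function(fit, stockIdValue, props = seq(0.05, 1, by = 0.05)) {
  levs <- levels(fit@model$model$stock)
  if (!stockIdValue %in% levs)
    stop(sprintf("stock '%s' is not in the fit", stockIdValue), call. = FALSE)
  nd <- data.frame(prop = props, stock = factor(stockIdValue, levels = levs))
  data.frame(prop = props,
             lambda = exp(as.numeric(mgcv::predict.gam(fit@model, newdata = nd))))
}

#' Per-stock lambda at the abundance anchors
#'
#' Evaluates a stock's fitted curve at its own minimum observed proportion
#' of maximum abundance, at 40% of the maximum, and at the maximum, plus the
#' pairwise differences (min - 40, min - max, 40 - max). Positive
#' differences indicate lambda increasing as abundance declines (negative,
#' i.e. compensatory, density dependence). The 40% anchor is NA when the
#' stock never dropped to 40% of its maximum.
#'
#' @param fit a [DDFit-class].
#' @param stockIdValue stock label present in the fit.
#' @param minProp override for the stock's minimum observed proportion
#'   (defaults to the value recorded in the fit).
#' @return one-row data.frame: stock_id, min_prop, lam_min, lam_40, lam_max,
#'   d_min_40, d_min_max, d_40_max.
#' @export
lambdaAtAnchors <- function(fit, stockIdValue, minProp = NULL) {
  if (is.null(minProp)) {
    minProp <- fit@minProp[[stockIdValue]]
    if (is.null(minProp) || is.na(minProp))
      stop(sprintf("stock '%s' is not in the fit", stockIdValue), call. = FALSE)
  }
  has40 <- minProp <= 0.40
  props <- c(minProp, if (has40) 0.40, 1.0)
  lam <- stockCurve(fit, stockIdValue, props)$lambda
  lamMin <- lam[1]
  lam40 <- if (has40) lam[2] else NA_real_
  lamMax <- lam[length(lam)]
  data.frame(stock_id = stockIdValue, min_prop = minProp,
             lam_min = lamMin, lam_40 = lam40, lam_max = lamMax,
             d_min_40 = lamMin - lam40, d_min_max = lamMin - lamMax,
             d_40_max = lam40 - lamMax, stringsAsFactors = FALSE)
}

#' Anchor table for every stock in a fit
#'
#' @param fit a [DDFit-class].
#' @return data.frame with one [lambdaAtAnchors()] row per stock.
#' @export
anchorTable <- function(fit) {
  do.call(rbind, lapply(names(fit@minProp), function(s)
    lambdaAtAnchors(fit, s)))
}
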