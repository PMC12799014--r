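#' Solve the discrete Euler-Lotka equation
#'
#' Finds the unique positive root lambda of
#' \deqn{1 = \sum_{a=\nu}^{\omega} \lambda^{-a} s_a f_a \Delta x}
#' for a reconstructed annual schedule. The left-hand side is strictly
#' decreasing in lambda, so the root is unique; it equals the dominant
#' eigenvalue of the Leslie matrix built from the same survival and
#' fecundity schedules. The root is bracketed in [1e-6, 1e3] and refined to
#' a relative precision of about 1e-10.
#'
#' @param lt a [LifeTable-class].
#' @param includeFishing if TRUE (default) use the fishing-inclusive
#'   survivorship \code{sReal} (giving the realized growth rate); if FALSE
#'   use \code{sDem} (natural mortality only, the fishing-excluded rate).
#' @return the annual population growth rate lambda (scalar).
#' @examples
#' lt <- buildLifeTable(makeStationaryFixture(), 2004)
#' solveLambda(lt)                         # 1 (replacement)
#' solveLambda(lt, includeFishing = FALSE) # about 1.106
#' @export
solveLambda <- function(lt, includeFishing = TRUE) {
  s <- if (includeFishing) lt@sReal else lt@sDem
  solveLambdaCore(lt@ages, s, lt@fec)
}

# root of sum(terms * lambda^-ages) - 1 over the positive-term ages
solveLambdaCore <- function(ages, s, fec, lower = 1e-6, upper = 1e3) {
  terms <- s * fec
  keep <- terms > 0
  if (!any(keep))
    stop("no reproduction: all survivorship-weighted fecundities are zero",
         call. = FALSE)
  tt <- terms[keep]
  aa <- ages[keep]
  g <- function(lam) sum(tt * lam^(-aa)) - 1
  glo <- g(lower)
  ghi <- g(upper)
  if (glo < 0 || ghi > 0)
    stop(sprintf(paste0("Euler-Lotka root outside bracket [%g, %g]: ",
                        "g(lower) = %.3g, g(upper) = %.3g"),
                 lower, upper, glo, ghi), call. = FALSE)
  stats::uniroot(g, lower = lower, upper = upper, tol = 1e-12,
                 f.lower = glo, f.upper = ghi, maxiter = 2000L)$root
}
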