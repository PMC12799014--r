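# Independent oracles and small builders used across tests.

# Leslie-matrix oracle for the renewal equation: ages must start at 1 so the
# matrix age classes line up with the equation's age exponents. Dominant
# eigenvalue computed by base eigen(), independent of the package's root
# finder.
leslieDominant <- function(l, fec) {
  k <- length(l)
  L <- matrix(0, k, k)
  L[1, ] <- fec
  if (k > 1) for (a in 1:(k - 1)) L[a + 1, a] <- l[a]
  ev <- eigen(L, only.values = TRUE)$values
  max(Mod(ev))
}

# Minimal valid LifeTable from survival and fecundity vectors (ages 1..k),
# with identical with/without-fishing survivorship (F = 0).
makeBareLifeTable <- function(l, fec) {
  k <- length(l)
  s <- cumprod(c(1, l[-k]))
  reproductive <- which(fec > 0)
  new("LifeTable", stockId = "bare", year = 2000L, ages = seq_len(k),
      rps = 0, rpa = numeric(k), ns = numeric(k), fec = fec,
      f = numeric(k), m = 1 - l, z = 1 - l, l = l,
      sReal = s, sDem = s,
      nu = if (length(reproductive)) min(reproductive) else NA_integer_,
      omega = k, deltaX = 1, flags = character())
}

# Random valid life table (ages 1..k) for property-style sweeps.
randomLifeTable <- function() {
  k <- sample(2:8, 1)
  l <- runif(k, 0.2, 0.95)
  fec <- runif(k, 0, 3) * (runif(k) < 0.7)
  fec[k] <- runif(1, 0.5, 3)   # guarantee reproduction at some age
  makeBareLifeTable(l, fec)
}

# Stationary fixture schedules derived by hand (ages 1-3):
#   N = (1000, 800, 400), W = (1, 2, 4), Mat = (0, 1, 1), M = 0.2,
#   F = (0, 0.3, 0.3)  =>  SSB = 2*800 + 4*400 = 3200 kg, recruits 1000/yr,
#   RPS = 1000/3200 = 0.3125, fec = W * RPS on mature ages.
FIX <- list(
  ssb = 3200, rps = 0.3125,
  fec = c(0, 0.625, 1.25),
  lReal = c(0.8, 0.5, 0.5), lDem = c(0.8, 0.8, 0.8),
  sReal = c(1, 0.8, 0.4), sDem = c(1, 0.8, 0.64),
  # root of 0.5 x^-2 + 0.8 x^-3 = 1, frozen from uniroot at tol 1e-15
  lambdaDem = 1.106031858023647,
  r0WithF = 0.8 * 0.625 + 0.4 * 1.25,    # 1.0
  r0NoF = 0.8 * 0.625 + 0.64 * 1.25,     # 1.3
  lgWithF = (2 * 0.5 + 3 * 0.5) / 1.0,   # 2.5
  lgNoF = (2 * 0.5 + 3 * 0.8) / 1.3      # 2.6153846...
)
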