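# Independent oracles, implemented separately from the package code paths
# they check.

# Periodic cubic spline by direct solution of the cyclic tridiagonal system
# for the knot second derivatives, evaluated with the textbook piecewise
# cubic formula.
oraclePeriodicSpline <- function(x, y, xout, period = 360) {
  n <- length(x)
  h <- diff(c(x, x[1] + period))
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    im <- if (i == 1L) n else i - 1L
    ip <- if (i == n) 1L else i + 1L
    A[i, im] <- A[i, im] + h[im] / 6
    A[i, i] <- A[i, i] + (h[im] + h[i]) / 3
    A[i, ip] <- A[i, ip] + h[i] / 6
    b[i] <- (y[ip] - y[i]) / h[i] - (y[i] - y[im]) / h[im]
  }
  M <- solve(A, b)
  xe <- c(x, x[1] + period)
  ye <- c(y, y[1])
  Me <- c(M, M[1])
  t <- x[1] + (xout - x[1]) %% period
  i <- findInterval(t, xe, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n)
  hh <- xe[i + 1L] - xe[i]
  Me[i] * (xe[i + 1L] - t)^3 / (6 * hh) + Me[i + 1L] * (t - xe[i])^3 / (6 * hh) +
    (ye[i] / hh - Me[i] * hh / 6) * (xe[i + 1L] - t) +
    (ye[i + 1L] / hh - Me[i + 1L] * hh / 6) * (t - xe[i])
}

# AUC by explicit pair counting
oraclePairAUC <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Welch t statistic from the closed-form formula
oracleWelch <- function(a, b) {
  va <- var(a); vb <- var(b)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                   vb^2 / (length(b)^2 * (length(b) - 1)))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# brute-force window scan: extremum of a trace restricted to [lo, hi)
oracleWindowMin <- function(times, values, lo, hi) {
  best <- Inf
  for (i in seq_along(times)) {
    if (times[i] >= lo && times[i] < hi && values[i] < best)
      best <- values[i]
  }
  if (is.infinite(best)) NA_real_ else best
}

# cells of a random strain/timing scenario for the window property tests
randomTraceScenario <- function() {
  nf <- sample(20:60, 1)
  times <- sort(runif(nf, 0, 1000))
  cycleStart <- 0
  cycleEnd <- 1000
  avc <- runif(1, 250, 600)
  timing <- new("CardiacTiming", cycleStart = cycleStart,
                cycleEnd = cycleEnd, avc = avc,
                systoleLength = avc - cycleStart,
                midDiastole = avc + (cycleEnd - avc) / 2)
  list(times = times, strain = rnorm(nf, -8, 8), sr = rnorm(nf, -0.5, 1),
       timing = timing)
}
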