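# Independent numerical oracles, deliberately implemented by different
# routes than the package internals.

# cumulative trapezoid integral
indepCumtrapz <- function(t, y) {
  c(0, cumsum(diff(t) * (y[-length(y)] + y[-1]) / 2))
}

# frame averages of a finely sampled curve
indepFrameAvg <- function(t, y, starts, ends) {
  cum <- indepCumtrapz(t, y)
  (approx(t, cum, xout = ends)$y - approx(t, cum, xout = starts)$y) /
    (ends - starts)
}

# one-tissue model K1 exp(-k2 t) (x) cp by direct quadrature of the
# convolution integral at every grid point (O(n^2), no recursion)
indepConv1tcm <- function(K1, k2, t, cp) {
  n <- length(t)
  out <- numeric(n)
  for (j in 2:n) {
    tj <- t[j]
    integ <- K1 * exp(-k2 * (tj - t[1:j])) * cp[1:j]
    out[j] <- sum(diff(t[1:j]) * (integ[-j] + integ[-1]) / 2)
  }
  out
}

# Monte-Carlo power of the equal-variance two-sample t-test (one-tailed),
# vectorized over replicates
mcPowerTwoSampleT <- function(d, n, alpha = 0.05, R = 1e5, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * R), n, R)
  y <- matrix(rnorm(n * R, mean = d), n, R)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- (colSums(x^2) - n * mx^2) / (n - 1)
  vy <- (colSums(y^2) - n * my^2) / (n - 1)
  s2p <- (vx + vy) / 2
  tstat <- (my - mx) / sqrt(s2p * 2 / n)
  mean(tstat > qt(1 - alpha, 2 * n - 2))
}

# shared fixtures (built once per test run)
FS <- petkin::defaultFrameSchedule()
INPUT <- petkin::simulateInput()
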