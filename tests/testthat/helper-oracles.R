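# Independent oracles used by the tests; deliberately different algorithms
# from the package internals.

# 1-D minimum-cost transport between two integer-count histograms with the
# same total count: expand each histogram into per-observation bin indices,
# sort, and match in order (the classic optimal-transport solution on the
# line). Cost is in bin units per unit mass.
transportOracle <- function(countsA, countsB) {
  stopifnot(sum(countsA) == sum(countsB), sum(countsA) > 0)
  posA <- rep(seq_along(countsA), countsA)
  posB <- rep(seq_along(countsB), countsB)
  sum(abs(sort(posA) - sort(posB))) / sum(countsA)
}

# closed-form standard deviation of a normal truncated to (a, b)
truncNormSd <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  v <- 1 + (al * dnorm(al) - be * dnorm(be)) / Z -
    ((dnorm(al) - dnorm(be)) / Z)^2
  sigma * sqrt(v)
}

# random frequency vector of length k (sums to 1)
randomFreq <- function(k) {
  w <- runif(k)
  w / sum(w)
}

histFromFreq <- function(freq, lo = 0, hi = 90) {
  new("CouplingHistogram", domainLow = lo, domainHigh = hi,
      k = length(freq), frequencies = freq, nSource = 1000L)
}

# simulate a co-orientation scenario and return its decomposition
simDebias <- function(sigma, alpha, n, seed, k = 15) {
  s <- simulateCoorientation(orientationSimConfig(
    n = n, seed = seed, sigmaX = sigma, alpha = alpha))
  computeDeBias(s, k = k, seed = seed)
}
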