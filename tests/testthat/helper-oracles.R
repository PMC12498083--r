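# Independent oracles, deliberately written without touching the package's
# fitting or rarefaction code paths.

# Exhaustive grid-search maximiser of the Poisson log-likelihood for a
# 2-parameter mean function given inline (not via the catalogue): a coarse
# grid over the box bounds, refined around the best cell. Two refinement
# passes are needed because correlated parameter pairs (e.g. the Monod
# asymptote and half-saturation constant) put the optimum more than one
# coarse cell away from the best coarse point.
grid_search_loglik <- function(mean_fn, lower, upper, area, richness,
                               n_grid = 200) {
  loglik <- function(p1, p2) {
    mu <- mean_fn(area, p1, p2)
    if (any(!is.finite(mu)) || any(mu < 0)) return(-Inf)
    mu <- pmax(mu, 1e-10)
    sum(richness * log(mu) - mu - lgamma(richness + 1))
  }
  search <- function(lo, hi) {
    g1 <- seq(lo[1], hi[1], length.out = n_grid)
    g2 <- seq(lo[2], hi[2], length.out = n_grid)
    best <- c(-Inf, NA, NA)
    for (i in seq_along(g1)) {
      for (j in seq_along(g2)) {
        ll <- loglik(g1[i], g2[j])
        if (ll > best[1]) best <- c(ll, g1[i], g2[j])
      }
    }
    list(logL = best[1], par = best[2:3],
      step = c(diff(g1[1:2]), diff(g2[1:2])))
  }
  best <- search(lower, upper)
  for (pass in 1:2) {
    lo2 <- pmax(lower, best$par - 2 * best$step)
    hi2 <- pmin(upper, best$par + 2 * best$step)
    refined <- search(lo2, hi2)
    if (refined$logL > best$logL) best <- refined else break
  }
  best$logL
}

# Exact expected rarefied richness by full enumeration of all C(N, n)
# equally likely draws (feasible for N <= 12).
enumerate_rarefaction <- function(pool_counts, n) {
  tokens <- rep.int(seq_along(pool_counts), pool_counts)
  N <- length(tokens)
  if (n == 0) return(0)
  combos <- utils::combn(N, n)
  mean(apply(combos, 2, function(idx) length(unique(tokens[idx]))))
}
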