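# Passive-sampling null model: does richness exceed what random
# accumulation of occurrences from the regional pool, in proportion to lake
# area, would produce? Expected rarefied richness uses the classic
# hypergeometric formula; a Monte-Carlo envelope gives per-lake 95% bounds.

#' Expected rarefied species richness
#'
#' Classic hypergeometric rarefaction: drawing `n` of the `N` occurrence
#' records of a pool in which species `j` has `N_j` records, the expected
#' species count is `sum_j [1 - C(N - N_j, n) / C(N, n)]`, evaluated in log
#' space (`lchoose`) to avoid overflow.
#'
#' @param pool_counts per-species occurrence counts (positive integers).
#' @param n number of records drawn, `0 <= n <= sum(pool_counts)`.
#' @return expected number of species represented in the draw.
#' @export
rarefaction_expected <- function(pool_counts, n) {
  stopifnot(all(pool_counts > 0), all(pool_counts == round(pool_counts)))
  N <- sum(pool_counts)
  if (n < 0 || n > N) {
    stop(sprintf("draw size n = %s outside [0, %d]", n, N), call. = FALSE)
  }
  if (n == 0) return(0)
  sum(1 - exp(lchoose(N - pool_counts, n) - lchoose(N, n)))
}

#' Area-proportional sampling effort (largest-remainder apportionment)
#'
#' Allocates `total` draws across lakes proportionally to area, rounded with
#' the largest-remainder method so the allocations sum exactly to `total`.
#'
#' @param area lake areas.
#' @param total total number of draws to allocate.
#' @return integer vector of per-lake efforts summing to `total`.
#' @export
area_proportional_effort <- function(area, total) {
  raw <- area / sum(area) * total
  n <- floor(raw)
  rem <- total - sum(n)
  if (rem > 0) {
    frac <- raw - n
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n[top] <- n[top] + 1
  }
  as.integer(n)
}

#' Passive-sampling test from raw vectors
#'
#' Core routine behind [passive_sampling_test()]: given per-lake observed
#' richness and a regional pool, computes each lake's expected rarefied
#' richness at an area-proportional effort, a Monte-Carlo 95% envelope, and
#' flags lakes whose observed richness exceeds the upper envelope.
#'
#' @param area lake areas (km^2).
#' @param observed observed per-lake richness.
#' @param pool_counts per-species occurrence counts defining the pool.
#' @param reps Monte-Carlo replicates (>= 200).
#' @param seed integer seed.
#' @param effort optional integer efforts per lake; default
#'   [area_proportional_effort()] with `total = sum(pool_counts)`.
#' @return data frame per lake: `n_effort`, `expected`, `lo`, `hi`
#'   (2.5%/97.5% quantiles), `observed`, `excess`, `flagged`.
#' @export
passive_sampling_core <- function(area, observed, pool_counts, reps = 1000,
                                  seed = 1, effort = NULL) {
  if (!length(pool_counts) || sum(pool_counts) == 0) {
    stop("species pool is empty", call. = FALSE)
  }
  if (reps < 200) stop("reps must be >= 200", call. = FALSE)
  N <- sum(pool_counts)
  if (is.null(effort)) effort <- area_proportional_effort(area, N)
  stopifnot(length(effort) == length(area), all(effort <= N))

  token_species <- rep.int(seq_along(pool_counts), pool_counts)
  rng <- local_rng(seed)
  on.exit(rng())

  expected <- vapply(effort, function(n) rarefaction_expected(pool_counts, n), 0)
  lo <- hi <- numeric(length(area))
  for (i in seq_along(area)) {
    if (effort[i] == 0) { lo[i] <- hi[i] <- 0; next }
    draws <- vapply(seq_len(reps), function(r) {
      length(unique(token_species[sample.int(N, effort[i])]))
    }, 0L)
    q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 1)
    lo[i] <- q[1]; hi[i] <- q[2]
  }
  data.frame(n_effort = effort, expected = expected, lo = lo, hi = hi,
    observed = observed, excess = observed - expected,
    flagged = observed > hi)
}

#' Passive-sampling null test for a lake dataset
#'
#' Builds the regional pool from each species' number of occupied lakes in
#' the original community (OC), allocates sampling effort proportionally to
#' lake area (total effort = total observed occurrences), and asks, per
#' lake, whether the observed OC richness exceeds the 97.5% quantile of
#' richness under random accumulation from that pool.
#'
#' @param lakes validated lake table.
#' @param occ validated occurrence table.
#' @param reps Monte-Carlo replicates (default 1000).
#' @param seed integer seed.
#' @param scenario community scenario defining the pool and the observed
#'   richness (default `"OC"`).
#' @return data frame per lake (`lake_id`, `area_km2`, plus the columns of
#'   [passive_sampling_core()]).
#' @export
passive_sampling_test <- function(lakes, occ, reps = 1000, seed = 1,
                                  scenario = "OC") {
  members <- occ[scenario_members(occ, scenario), , drop = FALSE]
  pool_counts <- as.integer(table(members$species_id))
  observed <- scenario_richness(occ, lakes, scenario)$richness
  res <- passive_sampling_core(lakes$area_km2, observed, pool_counts,
    reps = reps, seed = seed)
  cbind(data.frame(lake_id = lakes$lake_id, area_km2 = lakes$area_km2,
    stringsAsFactors = FALSE), res)
}

#' Generate an archipelago by pure passive sampling
#'
#' Draws each lake's community as a random area-proportional sample of the
#' pool's occurrence records, i.e. data that satisfy the passive-sampling
#' null by construction (used to calibrate the test's false-flag rate).
#'
#' @param area lake areas.
#' @param pool_counts per-species occurrence counts.
#' @param seed integer seed.
#' @param effort optional per-lake efforts (default area-proportional).
#' @return integer vector of per-lake richness.
#' @export
sample_passive_archipelago <- function(area, pool_counts, seed = 1,
                                       effort = NULL) {
  N <- sum(pool_counts)
  if (is.null(effort)) effort <- area_proportional_effort(area, N)
  token_species <- rep.int(seq_along(pool_counts), pool_counts)
  rng <- local_rng(seed)
  on.exit(rng())
  vapply(effort, function(n) {
    if (n == 0) 0L else length(unique(token_species[sample.int(N, n)]))
  }, 0L)
}
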