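# Stochastic island-biogeography simulator: colonisation from a mainland
# pool, per-lineage extinction scaling with lake area, and in-situ
# speciation (anagenesis and cladogenesis), run as an exact event-driven
# (Gillespie) birth-death process per lake. Used to ask how fast a steep
# ISAR assembles on a newly formed lake archipelago.

#' Configuration for the colonisation-speciation-extinction simulator
#'
#' Rates are per lineage per million years (My). Extinction scales with
#' lake area as `mu(A) = mu0 * A^(-x)`; immigration and speciation rates
#' optionally decline linearly to zero as richness approaches a cap `K`.
#'
#' @param M mainland pool size (species).
#' @param gamma per-species immigration rate (each absent mainland species
#'   colonises at this rate).
#' @param lambda_c per-lineage cladogenesis rate (adds an endemic).
#' @param lambda_a per-lineage anagenesis rate (converts a non-endemic
#'   immigrant population into an endemic species, freeing its mainland
#'   source to recolonise).
#' @param mu0 baseline per-lineage extinction rate at A = 1 km^2.
#' @param x extinction-area scaling exponent (>= 0).
#' @param K optional per-lake diversity cap.
#' @param t_end simulated age (My).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(M = 100, gamma = 0.01, lambda_c = 0.1,
                       lambda_a = 0.1, mu0 = 1, x = 0.25, K = NULL,
                       t_end = 1) {
  stopifnot(M >= 1, gamma >= 0, lambda_c >= 0, lambda_a >= 0, mu0 >= 0,
    x >= 0, t_end > 0)
  if (!is.null(K)) stopifnot(K >= 1)
  structure(list(M = as.integer(M), gamma = gamma, lambda_c = lambda_c,
    lambda_a = lambda_a, mu0 = mu0, x = x, K = K, t_end = t_end),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: M = %d, gamma = %g, lambda_c = %g, lambda_a = %g, mu0 = %g, x = %g, K = %s, t_end = %g My\n",
    x$M, x$gamma, x$lambda_c, x$lambda_a, x$mu0, x$x,
    if (is.null(x$K)) "unset" else x$K, x$t_end))
  invisible(x)
}

#' Simulate one lake's community assembly
#'
#' Exact Gillespie simulation of a single lake: each absent mainland
#' species immigrates at rate `gamma`; every resident lineage (immigrant or
#' endemic) goes extinct at rate `mu0 * area^(-x)`; anagenesis converts an
#' immigrant lineage to an endemic at rate `lambda_a`; cladogenesis at rate
#' `lambda_c` splits a lineage, adding one endemic (an immigrant parent
#' yields two endemics and frees its mainland source). With a cap `K`,
#' immigration and speciation rates scale by `max(0, 1 - S/K)`.
#'
#' @param config a [sim_config()].
#' @param area lake area (km^2), > 0.
#' @param seed optional integer seed (deterministic output when set).
#' @param t_end override of `config$t_end` (My).
#' @param log logical; keep a per-event log (time, event)?
#' @return list with `richness`, `n_nonendemic`, `n_endemic`, `events`
#'   (named counts), and optionally `event_log`.
#' @export
simulate_lake <- function(config, area, seed = NULL, t_end = config$t_end,
                          log = FALSE) {
  stopifnot(inherits(config, "sim_config"), area > 0, t_end > 0)
  if (!is.null(seed)) {
    rng <- local_rng(seed)
    on.exit(rng())
  }
  mu <- config$mu0 * area^(-config$x)
  n_imm <- 0L; n_end <- 0L; t <- 0
  ev <- c(immigration = 0L, extinction_immigrant = 0L,
    extinction_endemic = 0L, anagenesis = 0L, cladogenesis_immigrant = 0L,
    cladogenesis_endemic = 0L)
  log_t <- numeric(0); log_e <- character(0)

  repeat {
    S <- n_imm + n_end
    cap <- if (is.null(config$K)) 1 else max(0, 1 - S / config$K)
    r_imm <- config$gamma * (config$M - n_imm) * cap
    r_ext <- mu * S
    r_ana <- config$lambda_a * n_imm * cap
    r_cla <- config$lambda_c * S * cap
    total <- r_imm + r_ext + r_ana + r_cla
    if (total <= 0) break
    t <- t + stats::rexp(1, total)
    if (t > t_end) break
    u <- stats::runif(1) * total
    if (u < r_imm) {
      n_imm <- n_imm + 1L
      ev["immigration"] <- ev["immigration"] + 1L
      what <- "immigration"
    } else if (u < r_imm + r_ext) {
      if (stats::runif(1) < n_imm / S) {
        n_imm <- n_imm - 1L
        ev["extinction_immigrant"] <- ev["extinction_immigrant"] + 1L
        what <- "extinction_immigrant"
      } else {
        n_end <- n_end - 1L
        ev["extinction_endemic"] <- ev["extinction_endemic"] + 1L
        what <- "extinction_endemic"
      }
    } else if (u < r_imm + r_ext + r_ana) {
      n_imm <- n_imm - 1L; n_end <- n_end + 1L
      ev["anagenesis"] <- ev["anagenesis"] + 1L
      what <- "anagenesis"
    } else {
      if (stats::runif(1) < n_imm / S) {
        n_imm <- n_imm - 1L; n_end <- n_end + 2L
        ev["cladogenesis_immigrant"] <- ev["cladogenesis_immigrant"] + 1L
        what <- "cladogenesis_immigrant"
      } else {
        n_end <- n_end + 1L
        ev["cladogenesis_endemic"] <- ev["cladogenesis_endemic"] + 1L
        what <- "cladogenesis_endemic"
      }
    }
    if (log) { log_t <- c(log_t, t); log_e <- c(log_e, what) }
  }
  out <- list(richness = n_imm + n_end, n_nonendemic = n_imm,
    n_endemic = n_end, events = ev, t_end = t_end, area = area)
  if (log) out$event_log <- data.frame(time = log_t, event = log_e,
    stringsAsFactors = FALSE)
  out
}

#' Simulate an archipelago of independent lakes
#'
#' Runs [simulate_lake()] independently for each area (lakes share the
#' mainland pool parameters but not migrants) and summarises the resulting
#' ISAR with the linearised power fit.
#'
#' @param config a [sim_config()].
#' @param areas vector of lake areas (km^2).
#' @param seed integer seed; lake `i` uses `seed + i - 1`.
#' @param t_end override of `config$t_end`.
#' @return list with `lakes` (data frame: area, richness, n_endemic),
#'   `z`, `intercept` (NA with fewer than 3 nonzero-richness lakes), and
#'   `t_end`.
#' @export
simulate_archipelago <- function(config, areas, seed = 1,
                                 t_end = config$t_end) {
  sims <- lapply(seq_along(areas), function(i) {
    simulate_lake(config, areas[i], seed = seed + i - 1, t_end = t_end)
  })
  lakes <- data.frame(
    area_km2 = areas,
    richness = vapply(sims, `[[`, 0L, "richness"),
    n_endemic = vapply(sims, `[[`, 0L, "n_endemic"))
  z <- intercept <- NA_real_
  if (sum(lakes$richness > 0) >= 3) {
    ll <- suppressWarnings(fit_linear_power(lakes$area_km2, lakes$richness))
    z <- ll$slope[1]; intercept <- ll$intercept[1]
  }
  list(lakes = lakes, z = z, intercept = intercept, t_end = t_end)
}

#' ISAR slope through time
#'
#' Replicated archipelago simulations at a ladder of system ages, tracking
#' the mean (and quantiles) of the log-log slope `z`, and the first age at
#' which the mean slope reaches a target steepness.
#'
#' @param config a [sim_config()].
#' @param areas lake areas (km^2).
#' @param ages increasing vector of ages (My).
#' @param reps replicate archipelagos per age.
#' @param seed integer seed.
#' @param z_threshold slope at which the crossing age is reported
#'   (default 0.25).
#' @return data frame per age: `age`, `mean_z`, `q025`, `q500`, `q975`,
#'   `n_valid` (replicates where `z` was defined; undefined slopes from
#'   empty archipelagos count as 0 in `mean_z` since no area signal
#'   exists); crossing age in `attr(, "crossing_age")` (`NA` if never
#'   reached).
#' @export
zslope_vs_age <- function(config, areas, ages, reps = 100, seed = 1,
                          z_threshold = 0.25) {
  stopifnot(!is.unsorted(ages), all(ages > 0))
  rows <- list()
  for (ai in seq_along(ages)) {
    zs <- vapply(seq_len(reps), function(r) {
      s <- simulate_archipelago(config, areas,
        seed = seed + (ai - 1) * reps * length(areas) + (r - 1) * length(areas),
        t_end = ages[ai])
      s$z
    }, 0)
    n_valid <- sum(!is.na(zs))
    z0 <- ifelse(is.na(zs), 0, zs)
    q <- stats::quantile(z0, c(0.025, 0.5, 0.975), names = FALSE)
    rows[[ai]] <- data.frame(age = ages[ai], mean_z = mean(z0),
      q025 = q[1], q500 = q[2], q975 = q[3], n_valid = n_valid)
  }
  out <- do.call(rbind, rows)
  cross <- out$age[out$mean_z >= z_threshold]
  attr(out, "crossing_age") <- if (length(cross)) cross[1] else NA_real_
  attr(out, "z_threshold") <- z_threshold
  out
}
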