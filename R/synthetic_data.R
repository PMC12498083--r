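# Synthetic lake-archipelago generator. Emulates the statistical structure
# of the peri-Alpine fish dataset -- 79 lakes in four catchments, areas
# spanning four orders of magnitude, native richness following an
# asymptotic SAR with Poisson noise, endemics concentrated in a few deep
# lakes, introductions whose absolute number (but not proportion) rises
# with richness/area, and rare anthropogenic extirpations -- so that every
# stage of the analysis can be exercised without external data. It makes
# no attempt to clone the real tables species-for-species.

#' Configuration of the synthetic-data generator
#'
#' Defaults encode the study conditions the generator emulates: 79 lakes
#' across the four catchments, areas log-uniform on 0.05-600 km^2, native
#' richness Poisson around a rational SAR with parameters (7.23, 1.44,
#' 0.04), depth-driven zero-inflated endemism, introductions proportional
#' to native richness, and 0-4 extirpations per lake.
#'
#' @param n_lakes number of lakes (>= 4).
#' @param catchment_weights named sampling weights for the four catchments.
#' @param area_range km^2 range of the log-uniform area distribution.
#' @param depth_pars intercept, slope and sd of
#'   `ln(max_depth) = a + b ln(area) + N(0, sd)`.
#' @param sar_model name of the true SAR form generating mean richness.
#' @param theta parameters of the true SAR form (catalogue order).
#' @param truncate logical: resample zero richness to a minimum of 1 fish
#'   species per lake (the real system has no fishless lakes). Disable for
#'   unbiased parameter-recovery experiments.
#' @param pool_size size of the shared in-basin native pool.
#' @param pool_decay geometric decay of species incidence weights
#'   (widespread species occupy many lakes; the skew rarefaction needs).
#' @param p_salmonid proportion of the native pool that is salmonid.
#' @param endem_intercept,endem_slope logistic coefficients of
#'   `P(lake hosts endemics)` on `ln(max_depth)`; defaults put endemics
#'   almost exclusively in deep lakes.
#' @param endem_rate expected endemics per unit `ln(max_depth)` given the
#'   lake hosts a radiation.
#' @param endem_max_frac cap on endemics as a fraction of native richness.
#' @param sister_frac fraction of endemic species labelled sister-lake
#'   (vs single-lake) endemics.
#' @param intro_rate expected non-native species per native species (keeps
#'   the introduced proportion independent of area while the absolute
#'   count rises with richness, hence area).
#' @param introduced_frac fraction of non-natives drawn from the
#'   out-of-basin pool (rest are within-region translocations).
#' @param out_pool_size size of the out-of-basin species pool.
#' @param ext_mean Poisson mean of per-lake extirpation counts.
#' @param ext_max hard cap on extirpations per lake.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(
    n_lakes = 79,
    catchment_weights = c(Rhine = 0.38, Rhone = 0.14, Po = 0.23,
      Danube = 0.25),
    area_range = c(0.05, 600),
    depth_pars = c(intercept = 2.3, slope = 0.45, sd = 0.6),
    sar_model = "rational",
    theta = c(c = 7.23, z = 1.44, d = 0.04),
    truncate = TRUE,
    pool_size = 75,
    pool_decay = 0.93,
    p_salmonid = 0.2,
    endem_intercept = -9,
    endem_slope = 2,
    endem_rate = 0.8,
    endem_max_frac = 0.35,
    sister_frac = 0.25,
    intro_rate = 0.3,
    introduced_frac = 0.6,
    out_pool_size = 40,
    ext_mean = 0.8,
    ext_max = 4) {
  stopifnot(n_lakes >= 4, all(area_range > 0), diff(area_range) > 0,
    pool_size >= 1, intro_rate >= 0, ext_mean >= 0, ext_max >= 0)
  stopifnot(setequal(names(catchment_weights), CATCHMENTS))
  structure(as.list(environment()), class = "generator_config")
}

#' Draw Poisson richness around a SAR curve
#'
#' @param area lake areas.
#' @param model_name catalogue name of the mean curve.
#' @param theta curve parameters.
#' @param seed integer seed.
#' @param truncate resample zeros to at least 1 (slightly biases the mean
#'   upward at tiny areas; keep `FALSE` for parameter recovery).
#' @return integer richness vector.
#' @export
simulate_richness <- function(area, model_name, theta, seed = 1,
                              truncate = FALSE) {
  model <- sar_model_definitions()[[model_name]]
  if (is.null(model)) stop("unknown model: ", model_name, call. = FALSE)
  mu <- sar_evaluate(model, unname(theta), area)
  rng <- local_rng(seed)
  on.exit(rng())
  s <- stats::rpois(length(area), mu)
  if (truncate) {
    for (i in which(s == 0)) {
      tries <- 0
      while (s[i] == 0 && tries < 100) {
        s[i] <- stats::rpois(1, mu[i]); tries <- tries + 1
      }
      if (s[i] == 0) s[i] <- 1L
    }
  }
  as.integer(s)
}

#' Generate a synthetic lake table
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return validated lake table with `max_depth_m`, `elevation_m` and
#'   `dist_refugium_km` features. When `n_lakes >= 4` every catchment is
#'   represented.
#' @export
generate_lakes <- function(config = generator_config(), seed = 1) {
  rng <- local_rng(seed)
  on.exit(rng())
  n <- config$n_lakes
  w <- config$catchment_weights[CATCHMENTS]
  catchment <- c(CATCHMENTS,
    sample(CATCHMENTS, n - 4, replace = TRUE, prob = w))
  catchment <- sample(catchment)  # shuffle so the forced four are not first
  lr <- log10(config$area_range)
  area <- 10^stats::runif(n, lr[1], lr[2])
  dp <- config$depth_pars
  depth <- exp(dp["intercept"] + dp["slope"] * log(area) +
    stats::rnorm(n, 0, dp["sd"]))
  validate_lakes(data.frame(
    lake_id = sprintf("lake_%03d", seq_len(n)),
    catchment = catchment,
    area_km2 = area,
    max_depth_m = round(depth, 1),
    elevation_m = round(stats::runif(n, 190, 800)),
    dist_refugium_km = round(stats::runif(n, 50, 600)),
    stringsAsFactors = FALSE))
}

#' Generate synthetic species and occurrence tables for a lake table
#'
#' Native richness is Poisson around the configured SAR curve; native
#' identities come from a shared pool with geometric incidence weights
#' (nested occupancy); endemics are added in deep lakes per the
#' zero-inflated depth model and count toward native richness;
#' introductions/translocations and extirpations are layered on top.
#'
#' @param lakes validated lake table (needs `max_depth_m` for the endemism
#'   model; lakes without it get depth imputed from area).
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return list with validated `species` and `occurrences` tables.
#' @export
generate_communities <- function(lakes, config = generator_config(),
                                 seed = 1) {
  rng <- local_rng(seed)
  on.exit(rng())
  n <- nrow(lakes)
  depth <- lakes$max_depth_m
  if (is.null(depth)) {
    dp <- config$depth_pars
    depth <- exp(dp["intercept"] + dp["slope"] * log(lakes$area_km2))
  }

  families <- c("Cyprinidae", "Percidae", "Cottidae", "Esocidae",
    "Lotidae", "Anguillidae", "Nemacheilidae", "Siluridae")
  pool <- data.frame(
    species_id = sprintf("nat_%03d", seq_len(config$pool_size)),
    family = ifelse(stats::runif(config$pool_size) < config$p_salmonid,
      "Salmonidae", sample(families, config$pool_size, replace = TRUE)),
    endemism_class = "none", pool_origin = "in_basin",
    stringsAsFactors = FALSE)
  out_pool <- data.frame(
    species_id = sprintf("int_%03d", seq_len(config$out_pool_size)),
    family = sample(c("Centrarchidae", "Salmonidae", "Gobiidae",
      "Cyprinidae"), config$out_pool_size, replace = TRUE),
    endemism_class = "none", pool_origin = "out_of_basin",
    stringsAsFactors = FALSE)
  w <- config$pool_decay^(seq_len(config$pool_size) - 1)

  model <- sar_model_definitions()[[config$sar_model]]
  mu <- sar_evaluate(model, unname(config$theta), lakes$area_km2)

  occ_rows <- list(); endemic_rows <- list()
  for (i in seq_len(n)) {
    s_i <- stats::rpois(1, mu[i])
    if (config$truncate) {
      tries <- 0
      while (s_i == 0 && tries < 100) {
        s_i <- stats::rpois(1, mu[i]); tries <- tries + 1
      }
      if (s_i == 0) s_i <- 1L
    }

    # depth-driven zero-inflated endemism
    n_end <- 0L
    if (config$endem_rate > 0 && s_i > 1) {
      p_rad <- stats::plogis(config$endem_intercept +
        config$endem_slope * log(max(depth[i], 1)))
      if (stats::runif(1) < p_rad) {
        n_end <- 1L + stats::rpois(1, config$endem_rate * log(max(depth[i], 1)))
        n_end <- min(n_end, max(1L, floor(config$endem_max_frac * s_i)))
      }
    }

    n_shared <- min(s_i - n_end, config$pool_size)
    shared <- if (n_shared > 0) {
      sample(pool$species_id, n_shared, prob = w)
    } else character(0)

    ends <- character(0)
    if (n_end > 0) {
      ends <- sprintf("end_%s_%02d", lakes$lake_id[i], seq_len(n_end))
      endemic_rows[[length(endemic_rows) + 1]] <- data.frame(
        species_id = ends,
        family = ifelse(stats::runif(n_end) < 0.8, "Salmonidae", "Cottidae"),
        endemism_class = ifelse(stats::runif(n_end) < config$sister_frac,
          "sister_lake", "single_lake"),
        pool_origin = "in_basin", stringsAsFactors = FALSE)
    }
    natives <- c(shared, ends)

    # non-natives: absolute count scales with richness, proportion does not
    n_int <- stats::rpois(1, config$intro_rate * s_i)
    intro <- character(0); transl <- character(0)
    if (n_int > 0) {
      n_out <- stats::rbinom(1, n_int, config$introduced_frac)
      intro <- sample(out_pool$species_id, min(n_out, config$out_pool_size))
      candidates <- setdiff(pool$species_id, shared)
      transl <- sample(candidates, min(n_int - n_out, length(candidates)))
    }

    # rare anthropogenic extirpations among natives
    n_ext <- min(stats::rpois(1, config$ext_mean), config$ext_max,
      length(natives) - 1L)
    n_ext <- max(n_ext, 0L)
    ext_ids <- if (n_ext > 0) sample(natives, n_ext) else character(0)

    occ_rows[[i]] <- data.frame(
      lake_id = lakes$lake_id[i],
      species_id = c(natives, transl, intro),
      origin = c(rep("native", length(natives)),
        rep("translocated", length(transl)),
        rep("introduced", length(intro))),
      extirpated = c(natives %in% ext_ids,
        rep(FALSE, length(transl) + length(intro))),
      stringsAsFactors = FALSE)
  }

  species <- validate_species(rbind(pool, out_pool,
    if (length(endemic_rows)) do.call(rbind, endemic_rows)))
  occ <- validate_occurrences(do.call(rbind, occ_rows), species = species,
    lakes = lakes)
  list(species = species, occurrences = occ)
}

#' Generate a complete synthetic dataset
#'
#' @param config a [generator_config()].
#' @param seed integer seed; lakes use `seed`, communities `seed + 1`.
#' @return list with `lakes`, `species`, `occurrences` (all validated).
#' @export
generate_dataset <- function(config = generator_config(), seed = 1) {
  lakes <- generate_lakes(config, seed = seed)
  comm <- generate_communities(lakes, config, seed = seed + 1)
  c(list(lakes = lakes), comm)
}
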