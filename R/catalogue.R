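# Catalogue of island species-area relationship (ISAR) model forms.
#
# Each model is a named functional form S = f(A; theta) for the expected
# richness of a lake of area A (km^2), together with a parameter-bound rule
# derived from a data summary, an analytic asymptote rule, and a shape class.
# Piecewise (threshold) forms operate on x = ln A with the mean kept on the
# natural richness scale, so they can be fitted by the same Poisson
# likelihood as the smooth forms.

MEAN_EPS <- 1e-10

#' Summary of a dataset used to build parameter bounds
#'
#' @param area lake areas (km^2), all > 0.
#' @param richness observed richness counts.
#' @return list with area/richness ranges and the interior 5-95% quantile
#'   range of ln(area) used to bound piecewise thresholds. If all areas are
#'   equal the threshold range is widened to +-1 around the common ln(area),
#'   with a warning.
#' @export
sar_data_summary <- function(area, richness) {
  stopifnot(all(area > 0), all(richness >= 0))
  lnA <- log(area)
  tq <- stats::quantile(lnA, c(0.05, 0.95), names = FALSE)
  if (diff(tq) < 1e-8) {
    warning("degenerate areas (all equal); widening threshold bounds")
    tq <- c(tq[1] - 1, tq[2] + 1)
  }
  list(A_min = min(area), A_max = max(area),
    S_min = min(richness), S_max = max(richness),
    T_lo = tq[1], T_hi = tq[2])
}

# Role-based box bounds. The blanket rule (richness-scale parameters in
# (1e-6, 2*S_max], exponents in (-5, 5], asymptotes in (1e-6, 5*S_max],
# thresholds inside the 5-95% ln-area quantiles) is extended with
# area-scale, rate and shape roles for parameters that do not live on the
# richness scale (e.g. the Monod half-saturation constant is an area).
role_bounds <- function(role, s) {
  switch(role,
    scale     = c(1e-6, 2 * max(s$S_max, 1)),          # richness-scale c, f
    asym      = c(1e-6, 5 * max(s$S_max, 1)),          # upper-bound d
    exponent  = c(-5, 5),                              # power-law z
    pos_exp   = c(1e-8, 5),                            # positive exponent
    rate      = c(1e-8, 5),                            # per-km^2 rate
    area      = c(1e-8, 2 * s$A_max),                  # area-scale constant
    frac      = c(1e-8, 1 - 1e-8),                     # ratio in (0,1)
    shape     = c(1e-8, 20),                           # dimensionless shape
    offset    = c(-20, 20),                            # free offset (link scale)
    pw_slope  = c(-20, 20),                            # slope on ln-area
    pw_int    = c(-5 * max(s$S_max, 1), 5 * max(s$S_max, 1)),
    threshold = c(s$T_lo, s$T_hi),
    stop("unknown bound role: ", role))
}

new_sar_model <- function(name, label, shape_class, params, roles, mean_fn,
                          asym_fn, piecewise = FALSE) {
  stopifnot(length(params) == length(roles))
  structure(list(
    name = name, label = label, shape_class = shape_class,
    param_names = params, k = length(params), roles = roles,
    mean_fn = mean_fn, asym_fn = asym_fn, piecewise = piecewise),
    class = "sar_model")
}

#' @export
print.sar_model <- function(x, ...) {
  cat(sprintf("SAR model '%s' (%s, %s): %d parameter(s): %s\n",
    x$name, x$label, x$shape_class, x$k,
    paste(x$param_names, collapse = ", ")))
  invisible(x)
}

# piecewise helpers on x = ln A (or raw A when log_area = FALSE)
pw_x <- function(A, log_area) if (log_area) log(A) else A

#' The full catalogue of SAR model forms
#'
#' Returns the ordered list of model-form definitions. The default
#' configuration enables 24 forms: 20 smooth curves spanning linear, convex,
#' asymptotic and sigmoid shapes, plus 4 piecewise (threshold) forms on
#' ln(area). The logistic-in-area form is defined but disabled by default;
#' membership can be changed via `models` or a YAML config (see
#' [read_model_config()]).
#'
#' @param models character vector of model names to enable, or `NULL` for
#'   the default set.
#' @param config optional path to a YAML config with a `models:` list and
#'   optional `bounds:` overrides.
#' @param log_area logical: piecewise forms take ln(area) as predictor
#'   (default `TRUE`); set `FALSE` to use raw area.
#' @return named list of `sar_model` objects.
#' @export
sar_models <- function(models = NULL, config = NULL, log_area = TRUE) {
  all <- sar_model_definitions(log_area = log_area)
  overrides <- NULL
  if (!is.null(config)) {
    cfg <- read_model_config(config)
    if (is.null(models)) models <- cfg$models
    overrides <- cfg$bounds
  }
  if (is.null(models)) models <- setdiff(names(all), "logistic")
  unknown <- setdiff(models, names(all))
  if (length(unknown)) {
    stop("unknown model name(s): ", paste(unknown, collapse = ", "),
      call. = FALSE)
  }
  out <- all[models]
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% names(out)) next
      out[[nm]]$bound_overrides <- overrides[[nm]]
    }
  }
  out
}

#' Read a model-catalogue YAML configuration
#'
#' The file may contain `models:` (list of enabled model names) and
#' `bounds:` (per-model, per-parameter `[lower, upper]` overrides).
#'
#' @param path YAML file path.
#' @return list with elements `models` and `bounds`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(models = unlist(cfg$models), bounds = cfg$bounds)
}

#' Box bounds for a model's parameters
#'
#' @param model a `sar_model`.
#' @param summary output of [sar_data_summary()].
#' @return matrix with rows `lower`, `upper` and one column per parameter.
#' @export
sar_bounds <- function(model, summary) {
  b <- vapply(model$roles, role_bounds, numeric(2), s = summary)
  dimnames(b) <- list(c("lower", "upper"), model$param_names)
  if (!is.null(model$bound_overrides)) {
    for (p in names(model$bound_overrides)) {
      if (p %in% colnames(b)) b[, p] <- unlist(model$bound_overrides[[p]])
    }
  }
  b
}

#' Evaluate a SAR model's expected richness
#'
#' @param model a `sar_model`.
#' @param theta numeric parameter vector (length `model$k`, catalogue order).
#' @param A areas (km^2), > 0.
#' @return expected richness, clamped below at 1e-10 so it can be used
#'   directly as a Poisson mean.
#' @export
sar_evaluate <- function(model, theta, A) {
  if (length(theta) != model$k) {
    stop(sprintf("model '%s' expects %d parameter(s), got %d",
      model$name, model$k, length(theta)), call. = FALSE)
  }
  pmax(model$mean_fn(A, theta), MEAN_EPS)
}

#' Asymptote of a SAR model
#'
#' Finite limit of the expected richness as area grows without bound, the
#' attained maximum for the hump-shaped persistence form, or `Inf` for
#' unbounded forms.
#'
#' @inheritParams sar_evaluate
#' @return a single number; `Inf` means unbounded.
#' @export
sar_asymptote <- function(model, theta) {
  if (length(theta) != model$k) {
    stop(sprintf("model '%s' expects %d parameter(s), got %d",
      model$name, model$k, length(theta)), call. = FALSE)
  }
  model$asym_fn(theta)
}

#' Seeded random starting values within bounds
#'
#' Draws `n_starts` parameter vectors uniformly within the model's box
#' bounds (thresholds inside the interior ln-area quantile range);
#' deterministic given the seed.
#'
#' @inheritParams sar_bounds
#' @param n_starts number of starting vectors (default 10).
#' @param seed integer seed.
#' @return matrix `n_starts` x `k` of parameter vectors.
#' @export
sar_start_values <- function(model, summary, n_starts = 10, seed = 1) {
  b <- sar_bounds(model, summary)
  rng <- local_rng(seed)
  on.exit(rng())
  m <- matrix(stats::runif(n_starts * model$k), nrow = n_starts)
  out <- sweep(sweep(m, 2, b["upper", ] - b["lower", ], "*"),
    2, b["lower", ], "+")
  colnames(out) <- model$param_names
  out
}

# Restore-on-exit RNG scoping so package functions do not clobber the
# caller's random stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# The model definitions -----------------------------------------------------

sar_model_definitions <- function(log_area = TRUE) {
  defs <- list(

    new_sar_model("linear", "Linear", "linear",
      c("c", "z"), c("scale", "pw_slope"),
      function(A, th) th[1] + th[2] * A,
      function(th) Inf),

    new_sar_model("power", "Power (Arrhenius)", "convex",
      c("c", "z"), c("scale", "exponent"),
      function(A, th) th[1] * A^th[2],
      function(th) Inf),

    new_sar_model("powerR", "Extended power (PowerR)", "convex",
      c("f", "c", "z"), c("scale", "scale", "exponent"),
      function(A, th) th[1] + th[2] * A^th[3],
      function(th) Inf),

    new_sar_model("exponential", "Exponential (Gleason)", "convex",
      c("c", "z"), c("scale", "pw_slope"),
      function(A, th) th[1] + th[2] * log(A),
      function(th) Inf),

    new_sar_model("kobayashi", "Kobayashi logarithmic", "convex",
      c("c", "z"), c("scale", "area"),
      function(A, th) th[1] * log(1 + A / th[2]),
      function(th) Inf),

    new_sar_model("p1", "Persistence function 1", "convex",
      c("c", "z", "d"), c("scale", "exponent", "rate"),
      function(A, th) th[1] * A^th[2] * exp(-th[3] * A),
      function(th) {
        # hump-shaped: attained maximum at A* = z/d when z, d > 0
        if (th[2] > 0 && th[3] > 0) {
          th[1] * (th[2] / th[3])^th[2] * exp(-th[2])
        } else if (th[2] <= 0 && th[3] > 0) {
          if (th[2] < 0) Inf else th[1]  # sup as A -> 0
        } else Inf
      }),

    new_sar_model("p2", "Persistence function 2", "convex",
      c("c", "z", "d"), c("scale", "exponent", "area"),
      function(A, th) th[1] * A^th[2] * exp(-th[3] / A),
      function(th) Inf),

    new_sar_model("negexpo", "Negative exponential", "asymptotic",
      c("d", "z"), c("asym", "rate"),
      function(A, th) th[1] * (1 - exp(-th[2] * A)),
      function(th) th[1]),

    new_sar_model("monod", "Monod", "asymptotic",
      c("d", "c"), c("asym", "area"),
      function(A, th) th[1] * A / (th[2] + A),
      function(th) th[1]),

    new_sar_model("rational", "Rational function", "asymptotic",
      c("c", "z", "d"), c("scale", "exponent", "rate"),
      function(A, th) (th[1] + th[2] * A) / (1 + th[3] * A),
      function(th) {
        if (th[3] <= 0) stop("rational asymptote requires d > 0")
        th[2] / th[3]
      }),

    new_sar_model("asymp", "Asymptotic regression", "asymptotic",
      c("d", "c", "z"), c("asym", "asym", "frac"),
      function(A, th) th[1] - th[2] * th[3]^A,
      function(th) th[1]),

    new_sar_model("chapman", "Chapman-Richards", "sigmoid",
      c("d", "z", "c"), c("asym", "rate", "shape"),
      function(A, th) th[1] * (1 - exp(-th[2] * A))^th[3],
      function(th) th[1]),

    new_sar_model("logistic", "Logistic (area scale)", "sigmoid",
      c("d", "z", "c"), c("asym", "rate", "offset"),
      function(A, th) th[1] / (1 + exp(-th[2] * A + th[3])),
      function(th) th[1]),

    new_sar_model("gompertz", "Gompertz", "sigmoid",
      c("d", "z", "c"), c("asym", "rate", "area"),
      function(A, th) th[1] * exp(-exp(-th[2] * (A - th[3]))),
      function(th) th[1]),

    new_sar_model("extreme", "Extreme value (log-area)", "sigmoid",
      c("d", "c", "z"), c("asym", "offset", "exponent"),
      function(A, th) th[1] * (1 - exp(-exp(th[2] + th[3] * log(A)))),
      function(th) th[1]),

    new_sar_model("weibull3", "Cumulative Weibull (3 par.)", "sigmoid",
      c("d", "c", "z"), c("asym", "shape", "pos_exp"),
      function(A, th) th[1] * (1 - exp(-th[2] * A^th[3])),
      function(th) th[1]),

    new_sar_model("weibull4", "Cumulative Weibull (4 par.)", "sigmoid",
      c("d", "c", "z", "f"), c("asym", "shape", "pos_exp", "shape"),
      function(A, th) th[1] * (1 - exp(-th[2] * A^th[3]))^th[4],
      function(th) th[1]),

    new_sar_model("mmf", "Morgan-Mercer-Flodin", "sigmoid",
      c("d", "c", "z"), c("asym", "shape", "exponent"),
      function(A, th) th[1] / (1 + th[2] * A^(-th[3])),
      function(th) if (th[3] <= 0) th[1] / (1 + th[2]) else th[1]),

    new_sar_model("lomolino", "Lomolino", "sigmoid",
      c("d", "c", "z"), c("asym", "shape", "area"),
      function(A, th) th[1] / (1 + th[2]^(log(th[3] / A))),
      function(th) th[1]),

    new_sar_model("betap", "Cumulative beta-P", "sigmoid",
      c("d", "c", "z", "f"), c("asym", "area", "pos_exp", "shape"),
      function(A, th) th[1] * (1 - (1 + (A / th[2])^th[3])^(-th[4])),
      function(th) th[1]),

    new_sar_model("heleg", "Heleg (logistic in log-area)", "sigmoid",
      c("c", "f", "z"), c("scale", "shape", "exponent"),
      function(A, th) th[1] / (th[2] + A^(-th[3])),
      function(th) if (th[3] <= 0) th[1] / (th[2] + 1) else th[1] / th[2]),

    new_sar_model("pw_cont1", "Piecewise: continuous, one threshold",
      "piecewise",
      c("c", "z1", "z2", "T1"), c("pw_int", "pw_slope", "pw_slope", "threshold"),
      function(A, th) {
        x <- pw_x(A, log_area)
        th[1] + th[2] * pmin(x, th[4]) + th[3] * pmax(x - th[4], 0)
      },
      function(th) {
        if (th[3] > 0) Inf
        else if (th[3] == 0) max(th[1] + th[2] * th[4], 0)
        else 0  # declining final segment; clamped mean tends to zero
      }, piecewise = TRUE),

    new_sar_model("pw_zslope1", "Piecewise: left-horizontal, one threshold",
      "piecewise",
      c("c", "z", "T1"), c("pw_int", "pw_slope", "threshold"),
      function(A, th) {
        x <- pw_x(A, log_area)
        th[1] + th[2] * pmax(x - th[3], 0)
      },
      function(th) {
        if (th[2] > 0) Inf else if (th[2] == 0) max(th[1], 0) else 0
      }, piecewise = TRUE),

    new_sar_model("pw_discont1", "Piecewise: discontinuous, one threshold",
      "piecewise",
      c("c1", "z1", "c2", "z2", "T1"),
      c("pw_int", "pw_slope", "pw_int", "pw_slope", "threshold"),
      function(A, th) {
        x <- pw_x(A, log_area)
        ifelse(x <= th[5], th[1] + th[2] * x, th[3] + th[4] * x)
      },
      function(th) {
        if (th[4] > 0) Inf else if (th[4] == 0) max(th[3], 0) else 0
      }, piecewise = TRUE),

    new_sar_model("pw_cont2", "Piecewise: continuous, two thresholds",
      "piecewise",
      c("c", "z1", "z2", "z3", "T1", "T2"),
      c("pw_int", "pw_slope", "pw_slope", "pw_slope", "threshold", "threshold"),
      function(A, th) {
        x <- pw_x(A, log_area)
        t1 <- min(th[5], th[6]); t2 <- max(th[5], th[6])
        th[1] + th[2] * pmin(x, t1) +
          th[3] * pmin(pmax(x - t1, 0), t2 - t1) +
          th[4] * pmax(x - t2, 0)
      },
      function(th) {
        if (th[4] > 0) return(Inf)
        t1 <- min(th[5], th[6]); t2 <- max(th[5], th[6])
        plateau <- th[1] + th[2] * t1 + th[3] * (t2 - t1)
        if (th[4] == 0) max(plateau, 0) else 0
      }, piecewise = TRUE)
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}
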