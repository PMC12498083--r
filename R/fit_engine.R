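# Poisson maximum-likelihood fitting of SAR model forms with multi-start
# bounded optimisation, AICc ranking and Akaike weights.
#
# The likelihood treats each lake's observed richness S_i as a Poisson draw
# with mean f(A_i; theta) given by the (untransformed) SAR curve. Bounds are
# enforced exactly by optimising on a logistic-transformed scale with a
# derivative-free simplex search, robust to the kinks of the piecewise
# threshold forms.

#' Poisson log-likelihood of observed richness counts
#'
#' `sum(S_i * log(lambda_i) - lambda_i - log(S_i!))`, with the factorial via
#' `lgamma`. Means are clamped below at 1e-10.
#'
#' @param s_obs nonnegative integer richness counts.
#' @param means expected richness values (same length).
#' @return the log-likelihood (a single number).
#' @export
poisson_loglik <- function(s_obs, means) {
  if (length(s_obs) != length(means)) {
    stop("s_obs and means must have equal length", call. = FALSE)
  }
  if (any(s_obs < 0) || any(s_obs != round(s_obs))) {
    stop("richness counts must be nonnegative integers", call. = FALSE)
  }
  if (any(means < 0)) return(-Inf)
  lam <- pmax(means, MEAN_EPS)
  sum(s_obs * log(lam) - lam - lgamma(s_obs + 1))
}

#' Corrected Akaike information criterion
#'
#' @param logL maximised log-likelihood.
#' @param k number of free parameters (thresholds included).
#' @param n number of observations; must exceed `k + 1`, otherwise `NA` is
#'   returned (the model is excluded from ranking).
#' @return AICc value, `-2 logL + 2k + 2k(k+1)/(n-k-1)`.
#' @export
aicc <- function(logL, k, n) {
  if (n <= k + 1) return(NA_real_)
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' @param aicc_values numeric vector; `Inf`/`NA` entries get weight 0.
#' @return weights summing to 1 over the finite entries.
#' @export
akaike_weights <- function(aicc_values) {
  finite <- is.finite(aicc_values)
  if (!any(finite)) stop("no finite AICc values", call. = FALSE)
  delta <- aicc_values - min(aicc_values[finite])
  w <- ifelse(finite, exp(-delta / 2), 0)
  w / sum(w)
}

# bounded <-> unbounded parameter transform (exact box constraints)
theta_from_u <- function(u, lower, upper) lower + (upper - lower) * stats::plogis(u)
u_from_theta <- function(theta, lower, upper) {
  p <- (theta - lower) / (upper - lower)
  stats::qlogis(pmin(pmax(p, 1e-7), 1 - 1e-7))
}

#' Fit one SAR model by Poisson maximum likelihood
#'
#' Runs a bounded derivative-free simplex search (Nelder-Mead on a
#' logistic-transformed parameter space) from `n_starts` seeded random
#' starting vectors and keeps the best solution; threshold parameters of
#' piecewise forms are optimised jointly as free parameters. Parameter
#' vectors giving a negative mean at any observed area are infeasible
#' (log-likelihood `-Inf`; a finite penalty steers the simplex back inside
#' the feasible region).
#'
#' @param model a `sar_model` from [sar_models()].
#' @param area lake areas (km^2).
#' @param richness observed richness counts (nonnegative integers).
#' @param seed integer seed controlling the random starts.
#' @param n_starts number of starts (default 10).
#' @param maxit maximum function evaluations per start.
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @return object of class `sar_fit`: list with `name`, `theta`, `logL`,
#'   `k`, `n`, `AICc`, `n_converged`, `best_start`, `fitted`, `converged`.
#' @export
sar_fit <- function(model, area, richness, seed = 1, n_starts = 10,
                    maxit = 5000, reltol = 1e-8) {
  stopifnot(length(area) == length(richness))
  if (any(area <= 0)) stop("areas must be positive", call. = FALSE)
  if (any(richness < 0) || any(richness != round(richness))) {
    stop("richness counts must be nonnegative integers", call. = FALSE)
  }
  n <- length(area)
  if (n < model$k + 2) {
    stop(sprintf("model '%s' needs at least %d lakes, got %d",
      model$name, model$k + 2, n), call. = FALSE)
  }

  summ <- sar_data_summary(area, richness)
  b <- sar_bounds(model, summ)
  lower <- b["lower", ]; upper <- b["upper", ]
  starts <- sar_start_values(model, summ, n_starts = n_starts, seed = seed)

  nll <- function(u) {
    th <- theta_from_u(u, lower, upper)
    mu <- model$mean_fn(area, th)
    if (any(!is.finite(mu))) return(1e12)
    neg <- mu < 0
    if (any(neg)) return(1e10 + sum(-mu[neg]))  # infeasible, graded penalty
    -sum(richness * log(pmax(mu, MEAN_EPS)) - mu - lgamma(richness + 1))
  }

  best <- NULL; n_conv <- 0L; best_start <- NA_integer_
  for (i in seq_len(n_starts)) {
    u0 <- u_from_theta(starts[i, ], lower, upper)
    opt <- tryCatch(
      stats::optim(u0, nll, method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    # one simplex restart from the solution guards against premature collapse
    opt2 <- tryCatch(
      stats::optim(opt$par, nll, method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = reltol)),
      error = function(e) opt)
    if (opt2$value <= opt$value) opt <- opt2
    if (opt$value < 1e9) n_conv <- n_conv + 1L else next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best_start <- i
    }
  }
  if (is.null(best)) {
    return(structure(list(name = model$name, model = model, theta = NULL,
      logL = -Inf, k = model$k, n = n, AICc = NA_real_, n_converged = 0L,
      best_start = NA_integer_, fitted = NULL, converged = FALSE),
      class = "sar_fit"))
  }

  theta <- theta_from_u(best$par, lower, upper)
  names(theta) <- model$param_names
  mu <- model$mean_fn(area, theta)
  logL <- poisson_loglik(richness, mu)
  structure(list(name = model$name, model = model, theta = theta,
    logL = logL, k = model$k, n = n, AICc = aicc(logL, model$k, n),
    n_converged = n_conv, best_start = best_start,
    fitted = pmax(mu, MEAN_EPS), converged = TRUE),
    class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("SAR fit: %s  (k = %d, n = %d)\n", x$name, x$k, x$n))
  if (!x$converged) {
    cat("  did not converge from any start\n")
    return(invisible(x))
  }
  cat("  theta:", paste(sprintf("%s = %.4g", names(x$theta), x$theta),
    collapse = ", "), "\n")
  cat(sprintf("  logL = %.4f, AICc = %.4f, converged starts = %d\n",
    x$logL, x$AICc, x$n_converged))
  invisible(x)
}

#' Fit and rank the full model catalogue
#'
#' Fits every enabled model by [sar_fit()] and ranks the converged fits by
#' AICc (ties broken by fewer parameters, then model name), attaching
#' Akaike weights. Non-converged models and models with too few lakes for
#' AICc (`n <= k + 1`) are excluded from the ranking but listed in the
#' `excluded` attribute with a reason; a single model failure never aborts
#' the table.
#'
#' @param area lake areas (km^2).
#' @param richness richness counts.
#' @param models model list from [sar_models()].
#' @param seed integer seed; model `i` uses `seed + i - 1` so the table is
#'   reproducible bitwise.
#' @param n_starts starts per model.
#' @return a `sar_ranking` data frame with columns `model`, `shape_class`,
#'   `k`, `logL`, `AICc`, `delta_AICc`, `weight`, `n_converged`, `params`;
#'   fitted objects in `attr(, "fits")`, exclusions in `attr(, "excluded")`.
#' @export
sar_fit_all <- function(area, richness, models = sar_models(), seed = 1,
                        n_starts = 10) {
  fits <- list(); excluded <- character()
  for (i in seq_along(models)) {
    m <- models[[i]]
    f <- tryCatch(
      sar_fit(m, area, richness, seed = seed + i - 1, n_starts = n_starts),
      error = function(e) conditionMessage(e))
    if (is.character(f)) {
      excluded[m$name] <- f
    } else if (!f$converged) {
      excluded[m$name] <- "no start converged"
    } else if (!is.finite(f$AICc)) {
      excluded[m$name] <- sprintf("AICc undefined (n = %d <= k + 1 = %d)",
        f$n, f$k + 1)
    } else {
      fits[[m$name]] <- f
    }
  }
  if (!length(fits)) stop("no model could be fitted", call. = FALSE)

  tab <- data.frame(
    model = vapply(fits, `[[`, "", "name"),
    shape_class = vapply(fits, function(f) f$model$shape_class, ""),
    k = vapply(fits, `[[`, 0L, "k"),
    logL = vapply(fits, `[[`, 0, "logL"),
    AICc = vapply(fits, `[[`, 0, "AICc"),
    n_converged = vapply(fits, `[[`, 0L, "n_converged"),
    params = vapply(fits, function(f)
      paste(sprintf("%s=%.6g", names(f$theta), f$theta), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  tab$weight <- akaike_weights(tab$AICc)
  ord <- order(tab$AICc, tab$k, tab$model)
  tab <- tab[ord, c("model", "shape_class", "k", "logL", "AICc",
    "delta_AICc", "weight", "n_converged", "params")]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  attr(tab, "excluded") <- excluded
  attr(tab, "n") <- length(area)
  class(tab) <- c("sar_ranking", "data.frame")
  tab
}

#' @export
print.sar_ranking <- function(x, ...) {
  cat(sprintf("SAR multimodel ranking (%d models, n = %d lakes)\n",
    nrow(x), attr(x, "n")))
  df <- as.data.frame(x)
  df$logL <- round(df$logL, 3); df$AICc <- round(df$AICc, 3)
  df$delta_AICc <- round(df$delta_AICc, 3); df$weight <- round(df$weight, 4)
  print(df[, setdiff(names(df), "params")], ...)
  exc <- attr(x, "excluded")
  if (length(exc)) {
    cat("excluded:", paste(sprintf("%s (%s)", names(exc), exc),
      collapse = "; "), "\n")
  }
  invisible(x)
}

#' Rank of a model in a ranking table
#' @param ranking a `sar_ranking`.
#' @param name model name.
#' @return integer position (1 = best) or `NA` if excluded.
#' @export
sar_rank_of <- function(ranking, name) {
  r <- match(name, ranking$model)
  if (is.na(r)) NA_integer_ else r
}

#' Leave-one-catchment-out robustness of the ranking
#'
#' Repeats the multimodel analysis once per group, each time excluding all
#' lakes of that group, as a robustness check on the identity of the
#' best-supported form.
#'
#' @inheritParams sar_fit_all
#' @param groups group label per lake (e.g. catchment).
#' @return named list of `sar_ranking` tables, one per excluded group.
#' @export
sar_loco <- function(area, richness, groups, models = sar_models(),
                     seed = 1, n_starts = 10) {
  groups <- as.character(groups)
  levels <- unique(groups)
  if (length(levels) < 2) {
    stop("need at least 2 groups to exclude one at a time", call. = FALSE)
  }
  out <- list()
  for (g in levels) {
    keep <- groups != g
    if (!any(keep)) stop(sprintf("group '%s' contains all lakes", g),
      call. = FALSE)
    out[[g]] <- sar_fit_all(area[keep], richness[keep], models = models,
      seed = seed, n_starts = n_starts)
  }
  out
}

#' Linearised power-model fit (log-log ordinary least squares)
#'
#' Fits `ln S = c + z ln A` by OLS, overall and optionally per group,
#' reporting the intercept on the natural-log scale and the slope `z` with
#' standard errors. Lakes with zero richness are excluded (with a warning
#' and a per-row exclusion count), since `ln 0` is undefined.
#'
#' @param area lake areas (km^2).
#' @param richness richness counts.
#' @param groups optional group label per lake; when given, the result has
#'   one row per group plus the overall `"all"` row.
#' @return data frame with columns `group`, `n`, `n_excluded`, `intercept`,
#'   `slope`, `intercept_se`, `slope_se`.
#' @export
fit_linear_power <- function(area, richness, groups = NULL) {
  one <- function(a, s, label) {
    pos <- s > 0
    n_exc <- sum(!pos)
    if (n_exc > 0) {
      warning(sprintf("%s: excluded %d lake(s) with zero richness from the log-log fit",
        label, n_exc))
    }
    if (sum(pos) < 3) {
      return(data.frame(group = label, n = sum(pos), n_excluded = n_exc,
        intercept = NA_real_, slope = NA_real_, intercept_se = NA_real_,
        slope_se = NA_real_, stringsAsFactors = FALSE))
    }
    fit <- stats::lm(log(s[pos]) ~ log(a[pos]))
    cf <- summary(fit)$coefficients
    if (nrow(cf) < 2) {  # rank-deficient: no area variation, slope undefined
      cf <- rbind(cf, c(NA_real_, NA_real_, NA, NA))
    }
    data.frame(group = label, n = sum(pos), n_excluded = n_exc,
      intercept = cf[1, 1], slope = cf[2, 1],
      intercept_se = cf[1, 2], slope_se = cf[2, 2],
      stringsAsFactors = FALSE)
  }
  out <- one(area, richness, "all")
  if (!is.null(groups)) {
    groups <- as.character(groups)
    for (g in unique(groups)) {
      keep <- groups == g
      out <- rbind(out, one(area[keep], richness[keep], g))
    }
  }
  rownames(out) <- NULL
  out
}
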