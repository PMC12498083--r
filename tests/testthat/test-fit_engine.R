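test_that("Poisson log-likelihood matches hand evaluations", {
  # single count 3 with mean 3: 3 ln 3 - 3 - ln 6
  expect_equal(poisson_loglik(3, 3), 3 * log(3) - 3 - log(6),
    tolerance = 1e-12)
  expect_equal(round(poisson_loglik(3, 3), 4), -1.4959)
  # zero count under a near-zero mean is almost certain
  expect_equal(poisson_loglik(0, 1e-10), 0, tolerance = 1e-9)
  # additivity over independent lakes
  expect_equal(poisson_loglik(c(2, 2), c(2, 2)), 2 * poisson_loglik(2, 2))
  # negative means are infeasible, not an error
  expect_equal(poisson_loglik(c(1, 2), c(1, -3)), -Inf)
  expect_error(poisson_loglik(c(1, -2), c(1, 1)), "nonnegative integers")
  expect_error(poisson_loglik(c(1.5), c(1)), "nonnegative integers")
})

test_that("AICc closed form and small-sample behaviour", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_equal(round(aicc(0, 2, 10), 6), 5.714286)
  expect_equal(aicc(0, 2, 1e9), 4, tolerance = 1e-6)   # reduces to AIC
  expect_equal(aicc(-10, 3, 79), 20 + 6 + 24 / 75)
  expect_equal(round(aicc(-10, 3, 79), 2), 26.32)
  expect_true(is.na(aicc(0, 5, 6)))                    # n <= k + 1
})

test_that("Akaike weights are the softmax of -delta/2", {
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  expect_equal(akaike_weights(c(10, Inf)), c(1, 0))
  w <- akaike_weights(c(10, 12))
  expect_equal(w, c(plogis(1), 1 - plogis(1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  expect_equal(sum(akaike_weights(c(3, 9, 4, NA))), 1)
  expect_error(akaike_weights(c(Inf, NA)), "no finite")
})

test_that("constant richness data recover a flat power curve", {
  area <- exp(seq(log(0.1), log(500), length.out = 30))
  f <- sar_fit(sar_models()$power, area, rep(7L, 30), seed = 3)
  expect_lt(abs(f$theta[["z"]]), 0.02)
  expect_equal(f$theta[["c"]], 7, tolerance = 0.02)
})

test_that("multi-start optimiser matches an exhaustive grid-search oracle", {
  set.seed(71)
  area <- exp(runif(20, log(0.05), log(600)))
  s_power <- rpois(20, 5 * area^0.25)
  s_monod <- rpois(20, 34 * area / (6 + area))
  summ <- sar_data_summary(area, s_power)
  m <- sar_models()

  fit_p <- sar_fit(m$power, area, s_power, seed = 2)
  b <- sar_bounds(m$power, summ)
  oracle_p <- grid_search_loglik(function(A, c, z) c * A^z,
    b["lower", ], b["upper", ], area, s_power)
  expect_equal(fit_p$logL, oracle_p, tolerance = 1e-3)
  expect_gte(fit_p$logL, oracle_p - 1e-3)  # optimiser at least as good

  fit_m <- sar_fit(m$monod, area, s_monod, seed = 2)
  b <- sar_bounds(m$monod, sar_data_summary(area, s_monod))
  oracle_m <- grid_search_loglik(function(A, d, c) d * A / (c + A),
    b["lower", ], b["upper", ], area, s_monod)
  expect_equal(fit_m$logL, oracle_m, tolerance = 1e-3)
  expect_gte(fit_m$logL, oracle_m - 1e-3)
})

test_that("power-curve parameters are recovered from large simulated data", {
  area <- exp(seq(log(0.05), log(600), length.out = 500))
  s <- simulate_richness(area, "power", c(c = 5, z = 0.25), seed = 17)
  f <- sar_fit(sar_models()$power, area, s, seed = 4)
  expect_equal(f$theta[["z"]], 0.25, tolerance = 0.05)
  expect_equal(f$theta[["c"]], 5, tolerance = 0.4)
})

test_that("recovery error shrinks as the number of lakes grows", {
  med_err <- function(n, reps = 15) {
    area <- exp(seq(log(0.05), log(600), length.out = n))
    errs <- vapply(seq_len(reps), function(r) {
      s <- simulate_richness(area, "rational",
        c(7.23, 1.44, 0.04), seed = 1000 + r)
      f <- sar_fit(sar_models()$rational, area, s, seed = r)
      mean(abs(f$theta - c(7.23, 1.44, 0.04)) / c(7.23, 1.44, 0.04))
    }, 0)
    median(errs)
  }
  expect_lt(med_err(500), med_err(60))
})

test_that("rankings are deterministic and robust to adding a model", {
  d <- generate_dataset(seed = 5)
  rich <- scenario_richness(d$occurrences, d$lakes, "OC")$richness
  area <- d$lakes$area_km2
  small <- sar_models(models = c("power", "monod"))
  r1 <- sar_fit_all(area, rich, models = small, seed = 9)
  r2 <- sar_fit_all(area, rich, models = small, seed = 9)
  expect_identical(r1$logL, r2$logL)
  expect_identical(r1$params, r2$params)

  # adding a further model leaves the others' logL unchanged and weights
  # renormalise to 1
  bigger <- sar_models(models = c("power", "monod", "exponential"))
  r3 <- sar_fit_all(area, rich, models = bigger, seed = 9)
  expect_equal(r3$logL[match("power", r3$model)],
    r1$logL[match("power", r1$model)])
  expect_equal(r3$logL[match("monod", r3$model)],
    r1$logL[match("monod", r1$model)])
  expect_equal(sum(r3$weight), 1, tolerance = 1e-9)
  expect_equal(sum(r1$weight), 1, tolerance = 1e-9)
  # AICc is sorted and deltas start at zero
  expect_false(is.unsorted(r3$AICc))
  expect_equal(r3$delta_AICc[1], 0)
})

test_that("leave-one-group-out reruns the analysis on the remaining lakes", {
  d <- generate_dataset(seed = 6)
  rich <- scenario_richness(d$occurrences, d$lakes, "OC")$richness
  area <- d$lakes$area_km2
  groups <- ifelse(seq_along(area) <= 40, "A", "B")
  small <- sar_models(models = c("power", "exponential"))
  loco <- sar_loco(area, rich, groups, models = small, seed = 3)
  expect_named(loco, c("A", "B"))
  direct <- sar_fit_all(area[groups != "B"], rich[groups != "B"],
    models = small, seed = 3)
  expect_equal(loco$B$logL, direct$logL)
  expect_error(sar_loco(area, rich, rep("A", length(area)), models = small),
    "at least 2 groups")
})

test_that("log-log power fit is exact on exact data and excludes zeros", {
  area <- c(0.5, 2, 10, 80, 300)
  s <- exp(1 + 0.3 * log(area))
  # lm warns about the 'essentially perfect fit' we constructed on purpose
  ll <- suppressWarnings(fit_linear_power(area, s))
  expect_equal(ll$intercept[1], 1.0, tolerance = 1e-10)
  expect_equal(ll$slope[1], 0.3, tolerance = 1e-10)

  s2 <- c(0, 3, 8, 20, 33)
  expect_warning(ll2 <- fit_linear_power(area, s2), "zero richness")
  expect_equal(ll2$n_excluded[1], 1)
  expect_equal(ll2$n[1], 4)

  groups <- c("a", "a", "a", "b", "b")
  ll3 <- suppressWarnings(fit_linear_power(area, s, groups))
  expect_equal(ll3$group, c("all", "a", "b"))
})
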