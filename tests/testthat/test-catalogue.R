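test_that("default catalogue has 24 forms, 4 of them piecewise", {
  m <- sar_models()
  expect_length(m, 24)
  expect_equal(sum(vapply(m, function(x) x$piecewise, TRUE)), 4L)
  expect_false("logistic" %in% names(m))
  # membership is configurable
  expect_length(sar_models(models = c("power", "rational", "logistic")), 3)
  expect_error(sar_models(models = "not_a_model"), "unknown model")
})

test_that("a YAML config controls membership and bound overrides", {
  cfg <- file.path(tempdir(), "models.yaml")
  writeLines(c("models:", "  - power", "  - rational", "bounds:",
    "  power:", "    z: [0.0, 1.0]"), cfg)
  m <- sar_models(config = cfg)
  expect_equal(names(m), c("power", "rational"))
  s <- sar_data_summary(c(1, 10, 100), c(5, 10, 20))
  b <- sar_bounds(m$power, s)
  expect_equal(unname(b[, "z"]), c(0, 1))
})

test_that("every form yields finite nonnegative means at sampled parameters", {
  s <- sar_data_summary(c(0.05, 1, 50, 600), c(4, 8, 20, 38))
  A <- c(0.05, 1, 10, 600)
  for (m in sar_model_definitions()) {
    starts <- sar_start_values(m, s, n_starts = 5, seed = 7)
    for (i in seq_len(nrow(starts))) {
      mu <- sar_evaluate(m, starts[i, ], A)
      expect_true(all(is.finite(mu)), info = m$name)
      expect_true(all(mu >= 0), info = m$name)
    }
  }
})

test_that("evaluate matches hand computations", {
  m <- sar_models()
  expect_equal(sar_evaluate(m$power, c(5, 0), c(0.1, 1, 500)), rep(5, 3))
  expect_equal(sar_evaluate(m$power, c(2, 0.5), 4), 4)
  # rational mean approaches z/d at large area
  expect_equal(sar_evaluate(m$rational, c(7.23, 1.44, 0.04), 1e8),
    1.44 / 0.04, tolerance = 1e-5)
  expect_error(sar_evaluate(m$power, c(1, 2, 3), 1), "2 parameter")
})

test_that("asymptote rules give z/d for the rational form and Inf for power", {
  m <- sar_models()
  expect_equal(sar_asymptote(m$rational, c(7.23, 1.443, 0.043)),
    1.443 / 0.043, tolerance = 1e-12)
  expect_equal(round(sar_asymptote(m$rational, c(7.23, 1.443, 0.043))), 34)
  expect_true(is.infinite(sar_asymptote(m$power, c(5, 0.25))))
  expect_true(is.infinite(sar_asymptote(m$linear, c(5, 0.1))))
  expect_equal(sar_asymptote(m$monod, c(30, 2)), 30)
  expect_error(sar_asymptote(m$rational, c(7, 1.4, -0.1)), "d > 0")
})

test_that("asymptotic forms never exceed their asymptote and converge to it", {
  m <- sar_models()
  cases <- list(
    rational = c(7.23, 1.44, 0.04), negexpo = c(30, 0.05),
    monod = c(34, 6), asymp = c(30, 25, 0.9), chapman = c(30, 0.02, 1.5),
    gompertz = c(30, 0.05, 10), weibull3 = c(30, 0.1, 0.8),
    weibull4 = c(30, 0.1, 0.8, 1.4), mmf = c(30, 5, 0.7),
    lomolino = c(30, 4, 20), betap = c(30, 10, 1.2, 0.8),
    extreme = c(30, -1, 0.5))
  A <- exp(seq(log(0.01), log(1e6), length.out = 400))
  for (nm in names(cases)) {
    asym <- sar_asymptote(m[[nm]], cases[[nm]])
    mu <- sar_evaluate(m[[nm]], cases[[nm]], A)
    expect_true(all(mu <= asym + 1e-9), info = nm)
    expect_equal(mu[length(mu)], asym, tolerance = 0.02, info = nm)
  }
  # heleg saturates at c/f
  expect_equal(sar_asymptote(m$heleg, c(60, 2, 0.8)), 30)
})

test_that("nested forms coincide numerically on a grid", {
  defs <- sar_model_definitions()
  A <- exp(seq(log(0.05), log(600), length.out = 50))
  # rational with d = 0 is the linear form
  expect_equal(sar_evaluate(defs$rational, c(3, 0.2, 0), A),
    sar_evaluate(defs$linear, c(3, 0.2), A))
  # 4-parameter Weibull with f = 1 collapses to the 3-parameter one
  expect_equal(sar_evaluate(defs$weibull4, c(30, 0.1, 0.8, 1), A),
    sar_evaluate(defs$weibull3, c(30, 0.1, 0.8), A))
  # power with z = 1 is proportional growth (linear through the origin)
  expect_equal(sar_evaluate(defs$power, c(2, 1), A), pmax(2 * A, 1e-10))
})

test_that("piecewise forms are continuous exactly where advertised", {
  defs <- sar_model_definitions()
  Tv <- 1.2; eps <- 1e-9
  A_lo <- exp(Tv - eps); A_hi <- exp(Tv + eps)
  cont <- list(
    pw_cont1 = c(5, 2, 0.5, Tv),
    pw_zslope1 = c(5, 2, Tv),
    pw_cont2 = c(5, 2, 1, 0.2, Tv, 3))
  for (nm in names(cont)) {
    lo <- sar_evaluate(defs[[nm]], cont[[nm]], A_lo)
    hi <- sar_evaluate(defs[[nm]], cont[[nm]], A_hi)
    expect_equal(lo, hi, tolerance = 1e-6, info = nm)
  }
  # the discontinuous variant jumps by the intercept difference at T
  th <- c(5, 2, 9, 2, Tv)  # same slope, intercepts differ by 4
  jump <- sar_evaluate(defs$pw_discont1, th, A_hi) -
    sar_evaluate(defs$pw_discont1, th, A_lo)
  expect_equal(jump, 4, tolerance = 1e-5)
})

test_that("start values are seeded, within bounds, thresholds interior", {
  s <- sar_data_summary(c(0.05, 1, 50, 600), c(4, 8, 20, 38))
  m <- sar_models()
  s1 <- sar_start_values(m$power, s, seed = 5)
  s2 <- sar_start_values(m$power, s, seed = 5)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(10L, 2L))
  expect_true(all(s1[, "c"] > 0 & s1[, "c"] <= 2 * 38))
  expect_true(all(s1[, "z"] > -5 & s1[, "z"] <= 5))

  pw <- sar_start_values(m$pw_cont1, s, seed = 5)
  lnA <- log(c(0.05, 1, 50, 600))
  expect_true(all(pw[, "T1"] > min(lnA) & pw[, "T1"] < max(lnA)))

  expect_warning(sar_data_summary(rep(2, 5), c(1, 2, 3, 4, 5)),
    "degenerate")
})
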