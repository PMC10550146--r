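test_that("oscillation_features recovers analytic half-periods", {
  # cos on [0, 2pi]: interior zero-crossings at pi/2, 3pi/2 -> HP = pi
  fx <- feature_fixture(cos, c(0, 2 * pi))
  ft <- oscillation_features(fx)
  expect_equal(ft$hp_zero, pi, tolerance = 1e-3)
  # sin on [0, 2pi]: interior extrema at pi/2 (max), 3pi/2 (min) -> HP = pi
  fx2 <- feature_fixture(sin, c(0, 2 * pi))
  ft2 <- oscillation_features(fx2)
  expect_equal(ft2$hp_extrema, pi, tolerance = 0.05)
  expect_equal(ft2$extrema_kind, c("max", "min"))
  # sin(2 pi t / 16) on [0, 48]: all zero-crossing HPs equal 8 days
  fx3 <- feature_fixture(function(t) sin(2 * pi * t / 16), c(0, 48))
  ft3 <- oscillation_features(fx3)
  expect_equal(ft3$hp_zero, rep(8, 4), tolerance = 1e-3)
  # constant difference: no events, empty HP lists (not an error)
  fx4 <- feature_fixture(function(t) rep(0.3, length(t)), c(0, 40))
  ft4 <- oscillation_features(fx4)
  expect_length(ft4$hp_zero, 0)
  expect_length(ft4$hp_extrema, 0)
})

test_that("half-periods are invariant to positive affine rescaling of d(t)", {
  g <- function(t) sin(t / 3) * exp(-t / 40)
  base <- oscillation_features(feature_fixture(g, c(0, 60)))
  for (c_ in c(0.1, 7)) {
    sc <- oscillation_features(feature_fixture(function(t) c_ * g(t), c(0, 60)))
    expect_equal(sc$hp_zero, base$hp_zero, tolerance = 1e-9)
  }
})

test_that("fit_individual: perfect exponential data is won by exponential", {
  t <- seq(5, 50, by = 5)
  prof <- data.frame(time = t, tv = 100 * exp(0.08 * t))
  f <- suppressWarnings(fit_individual(prof))
  expect_equal(f$model_id, "exponential")
  expect_gt(f$adjusted_r2[["exponential"]], 0.999999)
  expect_lt(f$residual_variance, 1e-10)
  expect_error(fit_individual(prof[1:4, ]), ">= 5")
})

test_that("winner on noisy gompertz data is gompertz for most seeds", {
  # logistic is excluded: gompertz and logistic sigmoids are near-equivalent
  # on noisy unit-scale data, so with both present they split the wins
  gp <- classical_params("gompertz", tv0 = 69, alpha = 0.12, beta = 0.04)
  t <- seq(7, 80, by = 3)
  set.seed(42)
  wins <- replicate(100, {
    y <- exp(log(predict_classical(gp, t)) + rnorm(length(t), 0, 0.08))
    suppressWarnings(fit_individual(
      data.frame(time = t, tv = y),
      candidates = c("linear", "exponential", "gompertz", "simeoni")))$model_id
  })
  expect_gte(mean(wins == "gompertz"), 0.9)
})

test_that("ks_uniformity is calibrated and detects degeneracy", {
  set.seed(1)
  p_unif <- replicate(40, ks_uniformity(runif(1000))$p_value)
  expect_gte(mean(p_unif > 0.05), 0.9)
  expect_lt(ks_uniformity(rep(0, 20))$p_value, 1e-10)
  expect_error(ks_uniformity(c(0.1, 0.5, 1.2, 0.3, 0.4)), "\\[0, 1\\]")
  expect_error(ks_uniformity(c(0.1, 0.5)), "at least 5")
})

test_that("null_hp_study: zero noise gives degenerate identical replicates", {
  t <- seq(5, 60, by = 5)
  prof <- data.frame(time = t, tv = 100 * exp(0.06 * t))
  fit <- suppressWarnings(fit_individual(prof))
  fit$residual_variance <- 0    # degenerate null on the literal unit scale
  # every replicate is identical: the pool of 5 replicates is 5 copies of the
  # single-replicate pool
  n1 <- null_hp_study(list(fit), list(oscillation_features(fit)),
                      n_sims = 1, seed = 1, noise = "unit")
  n5 <- null_hp_study(list(fit), list(oscillation_features(fit)),
                      n_sims = 5, seed = 1, noise = "unit")
  expect_equal(length(n5$null_hp[[1]]), 5 * length(n1$null_hp[[1]]))
  expect_equal(sort(unique(round(n5$null_hp[[1]], 9))),
               sort(unique(round(n1$null_hp[[1]], 9))))
  # genuinely oscillatory observed HPs (well beyond the degenerate pool's
  # numerical wiggles) land at percentile 0
  osc <- oscillation_features(
    feature_fixture(function(x) sin(2 * pi * x / 30), c(5, 60)))
  ns <- null_hp_study(list(fit), list(osc), n_sims = 10, seed = 2,
                      noise = "unit")
  expect_true(all(ns$percentiles$percentile %in% c(0, 1)))
})

test_that("pooled simulated HP count scales roughly linearly with n_sims", {
  ds <- generate_population(final_spec(n_animals = 4), seed = 21)
  rep1 <- suppressWarnings(oscillation_screen(ds, n_sims = 40, seed = 5))
  rep2 <- suppressWarnings(oscillation_screen(ds, n_sims = 160, seed = 5))
  ratio <- rep2$null$n_sim_hp / rep1$null$n_sim_hp
  expect_gt(ratio, 2.6)
  expect_lt(ratio, 6.2)
})
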