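make_fit <- function(n = 15, sigma = 0.12, seed = 31, om = 0.2) {
  spec <- generation_spec(model = "exponential",
                          theta = classical_params("exponential", 80, k = 0.07),
                          omega = c(tv0 = om), sigma = sigma, n_animals = n,
                          schedule = seq(4, 60, by = 7), upper_limit = 1e9)
  ds <- generate_population(spec, seed = seed)
  list(ds = ds,
       fit = saem_fit(ds, nlme_spec("exponential",
                                    theta = classical_params("exponential",
                                                             60, k = 0.05),
                                    iiv = "tv0"),
                      saem_settings(n_explore = 150, n_smooth = 100),
                      seed = seed))
}

test_that("weighted residuals scale with sigma and are near-standard-normal", {
  mf <- make_fit(n = 25, seed = 33)
  res <- weighted_residuals(mf$fit)
  expect_equal(nrow(res), mf$ds$n_obs)
  # residuals of data simulated from (nearly) the generating model
  expect_lt(abs(mean(res$residual)), 0.15)
  expect_gt(sd(res$residual), 0.7)
  expect_lt(sd(res$residual), 1.3)
  # doubling sigma halves every residual
  fit2 <- mf$fit
  fit2$sigma <- 2 * fit2$sigma
  res2 <- weighted_residuals(fit2)
  expect_equal(res2$residual, res$residual / 2)
})

test_that("lag test: perfect negative series, sign-flip invariance, errors", {
  res <- data.frame(animal_id = rep("a", 20), time = 1:20,
                    residual = rep(c(1, -1), 10))
  out <- lag_autocorrelation_test(res, n_perm = 500, seed = 1)
  expect_equal(out$correlation, -1)
  expect_lt(out$p_value, 0.05)
  # invariant to a global sign flip
  res2 <- transform(res, residual = -residual)
  out2 <- lag_autocorrelation_test(res2, n_perm = 500, seed = 1)
  expect_equal(out2$correlation, out$correlation)
  expect_equal(out2$p_value, out$p_value)
  expect_error(lag_autocorrelation_test(
    data.frame(animal_id = "a", residual = rep(1, 12))), "constant")
  expect_error(lag_autocorrelation_test(res[1:5, ]), "at least 10")
})

test_that("lag test holds its size on iid residuals", {
  set.seed(77)
  rejections <- replicate(40, {
    res <- data.frame(animal_id = rep(sprintf("a%d", 1:8), each = 8),
                      residual = rnorm(64))
    lag_autocorrelation_test(res, n_perm = 300,
                             seed = sample.int(1e6, 1))$p_value < 0.05
  })
  expect_lte(mean(rejections), 0.15)
})

test_that("vpc collapses when variability vanishes and respects dropout", {
  mf <- make_fit(n = 12, seed = 35)
  fit <- mf$fit
  # degenerate: omega, sigma -> 0 collapses all bands onto the typical curve
  fit0 <- fit
  fit0$omega[] <- 1e-12
  fit0$sigma <- 1e-12
  v0 <- vpc(fit0, mf$ds, n_rep = 40, seed = 2, dropout = FALSE)
  expect_lt(max((v0$pi_hi - v0$pi_lo) / v0$pi_hi), 1e-6)

  # self-VPC: observed percentiles mostly inside their 95% PI
  v <- vpc(fit, mf$ds, n_rep = 150, seed = 3, dropout = FALSE)
  inside <- v$observed >= v$pi_lo & v$observed <= v$pi_hi
  expect_gte(mean(inside), 0.8)
  expect_true(all(v$pi_lo <= v$pi_hi))

  # dropout pulls the upper percentile down at late times
  ds_lim <- study_dataset(mf$ds$measurements, upper_limit = 700)
  v_drop <- vpc(fit, ds_lim, n_rep = 150, seed = 3, dropout = TRUE)
  v_free <- vpc(fit, ds_lim, n_rep = 150, seed = 3, dropout = FALSE)
  hi_drop <- v_drop[v_drop$percentile == 97.5, ]
  hi_free <- v_free[v_free$percentile == 97.5, ]
  ok <- which(is.finite(hi_drop$pi_hi) & is.finite(hi_free$pi_hi))
  last <- ok[which.max(hi_drop$t_mid[ok])]
  expect_lte(hi_drop$pi_hi[last], hi_free$pi_hi[last])
  # reproducible under the same seed
  v_rep <- vpc(fit, ds_lim, n_rep = 150, seed = 3, dropout = TRUE)
  expect_identical(v_drop, v_rep)
})
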