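# Population-fit machinery. Classical (closed-form) structural models keep
# these tests fast; the heavy final-model fits live in test-acceptance.R.

exp_spec <- function(n = 20, k = 0.07, tv0 = 80, om_tv0 = 0.25,
                     sigma = 0.15, schedule = seq(4, 60, by = 7)) {
  generation_spec(model = "exponential",
                  theta = classical_params("exponential", tv0, k = k),
                  omega = c(tv0 = om_tv0), sigma = sigma,
                  n_animals = n, schedule = schedule,
                  upper_limit = 1e9)
}

test_that("SAEM recovers a deterministic identifiable exponential exactly", {
  spec <- exp_spec(n = 8, om_tv0 = 0, sigma = 1e-6)
  ds <- generate_population(spec, seed = 2)
  fit <- saem_fit(ds, nlme_spec("exponential",
                                theta = classical_params("exponential", 60,
                                                         k = 0.05),
                                iiv = "tv0"),
                  saem_settings(n_explore = 200, n_smooth = 100), seed = 3)
  expect_lt(abs(fit$theta[["tv0"]] / 80 - 1), 1e-3)
  expect_lt(abs(fit$theta[["k"]] / 0.07 - 1), 1e-3)
})

test_that("SAEM matches the closed-form linear mixed model on log scale", {
  skip_if_not_installed("lme4")
  # exponential model with IIV on tv0 only is exactly a random-intercept
  # linear model in log space: log y = log tv0 + eta + k t + eps
  spec <- exp_spec(n = 40)
  ds <- generate_population(spec, seed = 4)
  fit <- saem_fit(ds, nlme_spec("exponential",
                                theta = classical_params("exponential", 60,
                                                         k = 0.05),
                                iiv = "tv0"),
                  saem_settings(n_explore = 250, n_smooth = 150), seed = 5)
  m <- ds$measurements
  lmm <- lme4::lmer(log(tv) ~ time + (1 | animal_id), data = m, REML = FALSE)
  beta <- lme4::fixef(lmm)
  vc <- as.data.frame(lme4::VarCorr(lmm))
  expect_lt(abs(log(fit$theta[["tv0"]]) - beta[[1]]), 0.02)
  expect_lt(abs(fit$theta[["k"]] - beta[[2]]), 0.002)
  expect_lt(abs(fit$omega[["tv0"]] - vc$sdcor[1]), 0.03)
  expect_lt(abs(fit$sigma - vc$sdcor[2]), 0.015)
})

test_that("SAEM is reproducible under a fixed seed", {
  spec <- exp_spec(n = 10)
  ds <- generate_population(spec, seed = 6)
  ns <- nlme_spec("exponential",
                  theta = classical_params("exponential", 60, k = 0.05))
  st <- saem_settings(n_explore = 60, n_smooth = 40)
  f1 <- saem_fit(ds, ns, st, seed = 9)
  f2 <- saem_fit(ds, ns, st, seed = 9)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$omega, f2$omega)
  expect_identical(f1$ebe, f2$ebe)
})

test_that("AIC follows its definition and penalizes a spurious IIV", {
  spec <- exp_spec(n = 25, om_tv0 = 0.3)
  ds <- generate_population(spec, seed = 7)
  st <- saem_settings(n_explore = 200, n_smooth = 100)
  # k has no IIV in truth; adding omega_k must not reduce AIC much
  f0 <- saem_fit(ds, nlme_spec("exponential",
                               theta = classical_params("exponential", 60,
                                                        k = 0.05),
                               iiv = "tv0"), st, seed = 8)
  f1 <- suppressWarnings(
    saem_fit(ds, nlme_spec("exponential",
                           theta = classical_params("exponential", 60,
                                                    k = 0.05),
                           iiv = c("tv0", "k")), st, seed = 8))
  f0 <- loglik_and_aic(f0, n_importance = 400, seed = 2)
  f1 <- loglik_and_aic(f1, n_importance = 400, seed = 2)
  expect_equal(f0$aic, -2 * f0$loglik + 2 * f0$n_par)
  expect_equal(f0$n_par, 4L)  # tv0, k, omega_tv0, sigma
  expect_equal(f1$n_par, 5L)
  # penalty dominates up to Monte-Carlo error in the two LL estimates
  expect_gt(f1$aic - f0$aic, -3 * (f0$loglik_se + f1$loglik_se) - 1)
})

test_that("IIV CV formula and RSE assembly match analytic references", {
  expect_equal(sqrt(exp(sqrt(log(1 + 0.29^2))^2) - 1), 0.29)
  expect_equal(sqrt(log(1 + 0.29^2)), 0.28417, tolerance = 1e-4)

  # linearized FIM against an independently coded analytic computation for
  # the exponential model (F columns: 1 and k t on the log-parameter scale)
  spec <- exp_spec(n = 30)
  ds <- generate_population(spec, seed = 11)
  fit <- saem_fit(ds, nlme_spec("exponential",
                                theta = classical_params("exponential", 60,
                                                         k = 0.05),
                                iiv = "tv0"),
                  saem_settings(n_explore = 150, n_smooth = 100), seed = 12)
  r <- rse_and_cv(fit)
  expect_identical(r$method, "fim")
  expect_equal(unname(r$cv), unname(sqrt(exp(fit$omega^2) - 1)))
  # independent analytic FIM for log tv0 (per-animal compound symmetry)
  A <- 0
  k <- fit$theta[["k"]]
  om2 <- fit$omega[["tv0"]]^2
  s2 <- fit$sigma^2
  for (i in seq_along(fit$times)) {
    tt <- fit$times[[i]]
    Fm <- cbind(1, k * tt)
    V <- om2 * tcrossprod(Fm[, 1]) + diag(s2, length(tt))
    A <- A + t(Fm) %*% solve(V) %*% Fm
  }
  se_an <- sqrt(diag(solve(A)))
  expect_equal(unname(r$rse_theta), unname(100 * se_an), tolerance = 0.15)
  expect_true(all(r$rse_theta > 0))
})
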