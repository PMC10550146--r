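test_that("equilibria: tumor-free family always, positive line only on the
           compatibility surface", {
  p <- published$theta
  eq <- equilibria(p)
  expect_false(eq$positive_exists)
  # condition arithmetic at the published values
  expect_equal(eq$condition_residual,
               0.11 * 0.00036 - 0.00069 * 0.0081, tolerance = 1e-12)
  ev <- eq$tumor_free$tumor_free_res1$eigenvalues
  expect_equal(sort(Re(ev)), sort(c(p$lambda - p$k_death, -p$k_death, 0)),
               tolerance = 1e-10)

  # engineer k_res k_ang = k_consumption k_death -> line of equilibria
  p2 <- final_model_params(tv0 = 100, lambda = 0.05, k_ang = 4e-4,
                           k_res = 0.1,
                           k_consumption = 0.1 * 4e-4 / 0.01,
                           k_death = 0.01)
  eq2 <- equilibria(p2)
  expect_true(eq2$positive_exists)
  expect_equal(eq2$positive_family$res_star, 0.01 / 0.05)
  st <- eq2$positive_family$representative
  expect_equal(unname(st["res"]), 0.2)
})

test_that("autc: closed forms and quadrature convergence", {
  tt <- seq(0, 100, by = 0.5)
  expect_equal(autc(data.frame(time = tt, tv = rep(3, length(tt)))), 300)
  expect_equal(autc(data.frame(time = tt, tv = tt)), 5000)
  expect_error(autc(data.frame(time = 0:50, tv = 0:50)), "cover")
  tr1 <- simulate_final_model(published$theta, seq(0, 100, by = 0.5))
  tr2 <- simulate_final_model(published$theta, seq(0, 100, by = 0.125))
  expect_lt(abs(autc(tr1) / autc(tr2) - 1), 1e-3)
})

test_that("ensemble: degenerate variances give identical trajectories,
           perturbed ensembles stay centered", {
  p <- published$theta
  e0 <- integrate_ensemble(p, times = seq(0, 40, 2), n = 5,
                           variances = c(tv = 0, ang = 0, res = 0), seed = 1)
  for (tr in e0$trajectories)
    expect_equal(tr$tv, e0$typical$tv, tolerance = 1e-12)
  e <- integrate_ensemble(p, times = seq(0, 40, 2), n = 200,
                          variances = c(tv = 1, ang = 0.1, res = 0.1),
                          seed = 2)
  m0 <- colMeans(e$inits)
  expect_equal(unname(m0), c(p$tv0, 1, 1), tolerance = 0.05)
})

test_that("local sensitivity: decoupled parameters have no effect", {
  # with lambda ~ 0, TV decays independently of the ANG/RES loop
  p <- final_model_params(tv0 = 100, lambda = 1e-14, k_ang = 3e-4,
                          k_res = 0.1, k_consumption = 7e-4, k_death = 0.01)
  s <- local_sensitivity(p, t_eval = 20)
  expect_lt(max(abs(s$pct_tv[s$parameter == "k_ang"])), 1e-6)
  expect_lt(max(abs(s$pct_tv[s$parameter == "k_res"])), 1e-6)
  # near-linear response: +/- perturbations of k_death have opposite signs
  kd <- s[s$parameter == "k_death", ]
  expect_lt(kd$pct_tv[kd$direction == "+"], 0)
  expect_gt(kd$pct_tv[kd$direction == "-"], 0)
})

test_that("sobol_saltelli recovers analytic indices of an additive function", {
  # y = 3 x1 + 1 x2 (+ inert x3): Si = 9/10, 1/10, 0; totals equal
  f <- function(U) 3 * U[, 1] + U[, 2] + 0 * U[, 3]
  ss <- sobol_saltelli(f, k = 3, n = 4000, seed = 5)
  expect_equal(ss$indices$first_order, c(0.9, 0.1, 0), tolerance = 0.05)
  expect_equal(ss$indices$total, c(0.9, 0.1, 0), tolerance = 0.05)
  # first-order <= total within estimator noise, for an interacting function
  g <- function(U) U[, 1] * U[, 2] + U[, 3]
  sg <- sobol_saltelli(g, k = 3, n = 4000, seed = 6)
  expect_true(all(sg$indices$first_order <= sg$indices$total + 0.05))
})

test_that("global exploration: degenerate span flagged; k_res x0.25 is the
           most shrinking single-parameter scenario", {
  p <- published$theta
  g0 <- global_exploration(p, n = 10, span = c(1, 1), n_sobol = 8, seed = 1)
  expect_true(g0$degenerate)
  expect_null(g0$sobol)
  expect_equal(max(abs(g0$scenarios$delta_autc)), 0, tolerance = 1e-6)

  sc <- treatment_scenarios(p)
  expect_equal(sc$delta_autc[sc$label == "reference"], 0)
  singles <- sc[grepl(" x", sc$label, fixed = TRUE), ]
  expect_equal(singles$label[which.min(singles$autc)], "k_res x0.25")
  expect_true(all(sc$autc >= 0))
})

test_that("scenario reference run reproduces simulate_final_model bit-for-bit", {
  p <- published$theta
  g <- global_exploration(p, n = 5, n_sobol = 8, seed = 2)
  tr <- simulate_final_model(p, seq(0, 100, by = 0.5))
  expect_identical(g$reference_autc, autc(tr, 0, 100))
})
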