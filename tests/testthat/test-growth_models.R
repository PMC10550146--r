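test_that("classical model predictions match closed forms and limits", {
  expect_equal(predict_classical(classical_params("exponential", 100, k = 0.1), 0),
               100)
  # gompertz plateau tv0 * exp(alpha / beta)
  gp <- classical_params("gompertz", 50, alpha = 0.1, beta = 0.05)
  expect_equal(predict_classical(gp, 1e4), 50 * exp(0.1 / 0.05),
               tolerance = 1e-8)
  # linear and logistic basics
  expect_equal(predict_classical(classical_params("linear", 10, k = 2),
                                 c(0, 5)), c(10, 20))
  lg <- classical_params("logistic", 10, k = 0.2, K = 100)
  expect_equal(predict_classical(lg, 0), 10)
  expect_lt(abs(predict_classical(lg, 1e3) - 100), 1e-6)
  expect_error(classical_params("gompertz", 50, alpha = 0.1), "beta")
})

test_that("simeoni growth matches exponential in the low-volume regime", {
  # lambda0 * TV << lambda1: switch never engages
  sp <- classical_params("simeoni", 1, l0 = 0.1, l1 = 1e6)
  t <- seq(0, 5, by = 0.5)
  expect_equal(predict_classical(sp, t), exp(0.1 * t), tolerance = 0.01)
  # and is monotone non-decreasing always
  sp2 <- classical_params("simeoni", 50, l0 = 0.08, l1 = 60)
  tv <- predict_classical(sp2, seq(0, 120, by = 1))
  expect_true(all(diff(tv) >= 0))
})

test_that("final model reduces to closed forms in decoupled limits", {
  eps <- 1e-15
  t <- seq(0, 50, by = 5)
  # pure decay: lambda ~ 0 -> TV = tv0 e^{-kd t}, ANG = e^{-kd t}
  p <- final_model_params(tv0 = 100, lambda = eps, k_ang = eps, k_res = eps,
                          k_consumption = eps, k_death = 0.05)
  tr <- simulate_final_model(p, t)
  expect_equal(tr$tv, 100 * exp(-0.05 * t), tolerance = 1e-6)
  expect_equal(tr$ang, exp(-0.05 * t), tolerance = 1e-6)
  # frozen resources -> pure exponential growth TV = tv0 e^{lambda t}
  p2 <- final_model_params(tv0 = 100, lambda = 0.05, k_ang = eps, k_res = eps,
                           k_consumption = eps, k_death = eps)
  tr2 <- simulate_final_model(p2, t)
  expect_equal(tr2$tv, 100 * exp(0.05 * t), tolerance = 1e-6)
})

test_that("solver converges: tightening tolerance changes TV by < 0.1%", {
  p <- published$theta
  t <- seq(0, 100, by = 1)
  a <- simulate_final_model(p, t, rtol = 1e-8, atol = 1e-10)
  b <- simulate_final_model(p, t, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(a$tv / b$tv - 1)), 1e-3)
})

test_that("published parameters give oscillatory dynamics with rising TV", {
  # the typical solution's oscillation lives in RES (and the TV growth rate);
  # TV itself rises monotonically at the published values
  tr <- simulate_final_model(published$theta, seq(0, 100, by = 0.25))
  dres <- diff(tr$res)
  expect_gte(sum(diff(sign(dres)) != 0), 2)       # RES oscillates
  rate <- diff(log(tr$tv))                          # growth rate oscillates
  expect_gte(sum(diff(sign(diff(rate))) != 0), 2)
  expect_true(all(diff(tr$tv) > 0))
  expect_false(attr(tr, "negative_state"))
})
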