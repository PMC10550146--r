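test_that("generator is deterministic and the truth record reproduces it", {
  spec <- final_spec(n_animals = 12)
  d1 <- generate_population(spec, seed = 5)
  d2 <- generate_population(spec, seed = 5)
  expect_identical(d1$measurements, d2$measurements)
  tr <- attr(d1, "truth")
  d3 <- generate_population(tr$spec, seed = tr$seed)
  expect_identical(d3$measurements, d1$measurements)
  expect_false(identical(generate_population(spec, seed = 6)$measurements,
                         d1$measurements))
})

test_that("degenerate spec collapses onto the typical curve", {
  spec <- generation_spec(omega = c(tv0 = 0)[0], sigma = 1e-9,
                          n_animals = 5, upper_limit = 1e9)
  ds <- generate_population(spec, seed = 1)
  typ <- simulate_final_model(final_model_defaults()$theta, spec$schedule)$tv
  for (pr in split_animals(ds))
    expect_equal(pr$tv, typ, tolerance = 1e-6)
})

test_that("dropout removes only suffixes, above-limit values never retained", {
  spec <- final_spec(n_animals = 30)
  ds <- generate_population(spec, seed = 9)
  expect_true(all(ds$measurements$tv <= spec$upper_limit))
  for (pr in split_animals(ds)) {
    k <- nrow(pr)
    expect_equal(pr$time, spec$schedule[seq_len(k)])
  }
})

test_that("default population lands near the study shape", {
  ds <- generate_population(final_spec(), seed = 1)
  expect_equal(ds$n_animals, 85L)
  expect_gt(ds$n_obs, 1064 * 0.75)
  expect_lt(ds$n_obs, 1064 * 1.25)
  expect_equal(length(unique(ds$measurements$cell_line)), 12L)
  expect_equal(length(unique(ds$measurements$tumor_type)), 6L)
})

test_that("empirical tv0 dispersion matches the log-normal IIV", {
  spec <- generation_spec(n_animals = 1000, schedule = c(0, 1),
                          sigma = 1e-9, upper_limit = 1e12)
  ds <- generate_population(spec, seed = 13)
  first <- vapply(split_animals(ds), function(pr) pr$tv[1], numeric(1))
  cv_emp <- sd(first) / mean(first)
  cv_target <- final_model_defaults()$iiv_cv[["tv0"]]
  expect_lt(abs(cv_emp / cv_target - 1), 0.1)
})

test_that("null generator requires a monotone model and is reproducible", {
  expect_error(generate_null_dataset(final_spec(), seed = 1), "monotone")
  spec <- gompertz_null_spec(n_animals = 6)
  d1 <- generate_null_dataset(spec, seed = 3)
  d2 <- generate_null_dataset(spec, seed = 3)
  expect_identical(d1$measurements, d2$measurements)
})
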