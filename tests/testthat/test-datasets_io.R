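test_that("study_dataset validates and orders measurements", {
  m <- data.frame(animal_id = c("b", "a", "a", "b"),
                  time = c(10, 7, 3, 3),
                  tv = c(200, 150, 100, 120))
  ds <- study_dataset(m, upper_limit = 2000)
  expect_equal(ds$n_animals, 2L)
  expect_equal(ds$n_obs, 4L)
  expect_equal(ds$measurements$animal_id, c("a", "a", "b", "b"))
  expect_equal(ds$measurements$time, c(3, 7, 3, 10))

  expect_error(study_dataset(transform(m, tv = c(200, 150, 0, 120))),
               "non-positive")
  expect_error(study_dataset(m[c(1, 1, 2, 3), ]), "duplicate")
  expect_error(study_dataset(m[1:3, ]), "fewer than 2")
  expect_error(study_dataset(m[, c("animal_id", "time")]), "missing column")
})

test_that("read/write round-trips a synthetic dataset through CSV", {
  ds <- generate_population(final_spec(n_animals = 10), seed = 3)
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  ds2 <- read_dataset(path, upper_limit = ds$upper_limit)
  expect_equal(ds2$measurements, ds$measurements, tolerance = 1e-12)
  expect_equal(ds2$n_animals, ds$n_animals)
  expect_equal(ds2$n_obs, ds$n_obs)
  # 3-row toy file, custom dialect
  toy <- tempfile(fileext = ".csv")
  writeLines(c("id;day;vol", "m1;1;50", "m1;4;80", "m1;8;160"), toy)
  ds3 <- read_dataset(toy, dialect = list(sep = ";", col_id = "id",
                                          col_time = "day", col_tv = "vol"))
  expect_equal(ds3$n_animals, 1L)
  expect_equal(ds3$n_obs, 3L)
  expect_error(read_dataset(toy), "format error")
})

test_that("caliper_volume implements length x width^2 / 2 with swap warning", {
  expect_equal(caliper_volume(10, 5), 125)
  expect_equal(caliper_volume(2, 2), 4)
  expect_equal(caliper_volume(8.4, 6.2), 161.448)
  expect_warning(v <- caliper_volume(5, 10), "swap")
  expect_equal(v, 125)
  expect_error(caliper_volume(-1, 2), "positive")
})

test_that("transform_profile handles unit and log modes", {
  expect_equal(transform_profile(c(100, 400, 200), "unit"),
               c(0.25, 1, 0.5))
  expect_equal(transform_profile(1, "log"), 0)
  expect_error(transform_profile(numeric(0)), "empty")
  expect_error(transform_profile(c(1, -2), "log"), "positive")
  # unit transform maps every animal's max to exactly 1
  ds <- generate_population(final_spec(n_animals = 20), seed = 7)
  for (pr in split_animals(ds)) {
    u <- transform_profile(pr$tv, "unit")
    expect_true(all(u > 0 & u <= 1))
    expect_equal(max(u), 1)
  }
})
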