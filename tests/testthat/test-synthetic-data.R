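test_that("zero noise reproduces the model output exactly", {
  fx <- glv2_fixture()
  ds <- generate_dataset(fx$model, fx$theta_nominal, fx$designs,
                         noise_model("proportional", 0), seed = 1)
  expect_equal(ds$value, ds$truth)
  expect_true(all(ds$sigma > 0))
})

test_that("identical seeds give identical datasets; different seeds differ", {
  fx <- glv2_fixture()
  nm <- noise_model("proportional", 0.1)
  a <- generate_dataset(fx$model, fx$theta_nominal, fx$designs, nm, seed = 7)
  b <- generate_dataset(fx$model, fx$theta_nominal, fx$designs, nm, seed = 7)
  c <- generate_dataset(fx$model, fx$theta_nominal, fx$designs, nm, seed = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$value, c$value))
})

test_that("proportional noise has the requested relative spread", {
  # 1e4 replicate draws at a single time point: empirical sd / |y| = level
  # within 3 Monte-Carlo standard errors, sd(sd_hat) ~ sd/sqrt(2(n-1))
  m <- logistic_model()
  om <- observation_map("fo", n_x = 1)
  # 1e4 records at the same sampling time = 1e4 independent replicate draws
  d <- experiment_design("e1", x0 = 0.5, t_span = c(0, 1),
                         sampling_times = rep(1, 10000), obs_map = om)
  level <- 0.10
  vals <- generate_dataset(m, c(1, -1), list(d),
                           noise_model("proportional", level),
                           seed = 123)$value
  y_true <- 1 / (1 + exp(-1))  # logistic from x0 = 0.5 at t = 1
  rel_sd <- sd(vals) / abs(y_true)
  mc_se <- level / sqrt(2 * (10000 - 1))
  expect_lt(abs(rel_sd - level), 3 * mc_se)
  expect_equal(mean(vals), y_true, tolerance = 4 * level / sqrt(10000) / y_true)
})

test_that("standardized residuals of a synthetic dataset are Gaussian", {
  fx <- glv3_fixture(t_grid = seq(0.25, 5, length.out = 40))
  ds <- generate_dataset(fx$model, fx$theta_nominal, fx$designs,
                         noise_model("proportional", 0.1), seed = 3)
  z <- (ds$value - ds$truth) / ds$sigma
  expect_gt(shapiro.test(z)$p.value, 0.01)
  expect_equal(mean(z), 0, tolerance = 3 / sqrt(length(z)))
  expect_equal(sd(z), 1, tolerance = 3 / sqrt(2 * length(z)))
})

test_that("blow-up at the nominal parameters names the failing experiment", {
  m <- logistic_model()
  om <- observation_map("fo", n_x = 1)
  d <- experiment_design("diverging_exp", x0 = 1, t_span = c(0, 3),
                         sampling_times = c(1, 2), obs_map = om)
  expect_error(
    generate_dataset(m, c(0, 1), list(d), noise_model("proportional", 0.05),
                     seed = 1),
    "diverging_exp")
})

test_that("dataset round trip through CSV + sidecar is lossless", {
  fx <- glv2_fixture()
  ds <- generate_dataset(fx$model, fx$theta_nominal, fx$designs,
                         noise_model("proportional", 0.05), seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(as.data.frame(back)[names(as.data.frame(ds))],
               as.data.frame(ds), ignore_attr = TRUE)
  prov <- attr(back, "provenance")
  expect_equal(prov$theta_nominal, as.numeric(fx$theta_nominal))
  expect_equal(prov$seed, 9L)
  # idempotence: a second round trip is identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(back, path2)
  expect_equal(as.data.frame(read_dataset(path2)), as.data.frame(back),
               ignore_attr = TRUE)
})

test_that("malformed files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("experiment,observable,time,value",
               "e1,y1,0.5,0.2"), path)
  expect_error(read_dataset(path), "sigma")
  writeLines(c("experiment,observable,time,value,sigma",
               "e1,y1,0.5,0.2,0.01",
               "e1,y1,1.0,not_a_number,0.01"), path)
  expect_error(read_dataset(path), "3")
  # header-only file reads back empty
  writeLines("experiment,observable,time,value,sigma", path)
  expect_equal(nrow(read_dataset(path)), 0)
})

test_that("splitting by experiment partitions the records", {
  fx <- glv2_fixture()
  ds <- generate_dataset(fx$model, fx$theta_nominal, fx$designs,
                         noise_model("proportional", 0.05), seed = 2)
  sp <- split_dataset(ds, "exp2")
  expect_equal(unique(sp$training$experiment), "exp1")
  expect_equal(unique(sp$validation$experiment), "exp2")
  expect_equal(nrow(sp$training) + nrow(sp$validation), nrow(ds))
  expect_equal(nrow(split_dataset(ds, character(0))$validation), 0)
  expect_error(split_dataset(ds, "nope"), "unknown experiment")
})
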