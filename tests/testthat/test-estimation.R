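make_glv2_problem <- function(noise_level = 0.05, seed = 42,
                              designs = NULL) {
  fx <- glv2_fixture()
  designs <- designs %||% fx$designs
  ds <- generate_dataset(fx$model, fx$theta_nominal, designs,
                         noise_model("proportional", noise_level),
                         seed = seed)
  list(fx = fx, ds = ds,
       problem = estimation_problem(fx$model, designs, ds))
}

test_that("weighted least-squares cost matches the hand-computed form", {
  # one record, ym = 3, y = 1, sigma = 2 -> J = ((3-1)/2)^2 = 1
  m <- drift_model()
  om <- observation_map("fo", n_x = 1)
  d <- experiment_design("e1", x0 = 0, t_span = c(0, 2),
                         sampling_times = 1, obs_map = om)
  ds <- tibble::tibble(experiment = "e1", observable = "y1",
                       time = 1, value = 3, sigma = 2)
  pr <- estimation_problem(m, list(d), ds)
  w <- wls_cost(pr, 1)  # y(1) = theta * t = 1
  expect_equal(w$J, 1)
  expect_equal(w$residuals, 1)

  # perfect prediction gives J = 0
  ds0 <- tibble::tibble(experiment = "e1", observable = "y1",
                        time = c(1, 2), value = c(1, 2), sigma = 1)
  pr0 <- estimation_problem(m, list(d), ds0)
  expect_equal(wls_cost(pr0, 1)$J, 0, tolerance = 1e-12)
})

test_that("the cost is additive over experiments", {
  s <- make_glv2_problem(0.1, seed = 5)
  J_both <- wls_cost(s$problem, s$fx$theta_nominal)$J
  J_each <- vapply(c("exp1", "exp2"), function(e) {
    sub <- s$ds[s$ds$experiment == e, ]
    pr <- estimation_problem(s$fx$model,
                             purrr::keep(s$fx$designs,
                                         ~ .x$experiment_id == e), sub)
    wls_cost(pr, s$fx$theta_nominal)$J
  }, numeric(1))
  expect_equal(J_both, sum(J_each), tolerance = 1e-10)
})

test_that("cost at nominal parameters has chi-squared scale", {
  # standardized residuals are iid N(0,1) at the truth, so E[J] = n_records
  Js <- vapply(1:12, function(s) {
    st <- make_glv2_problem(0.1, seed = 1000 + s)
    wls_cost(st$problem, st$fx$theta_nominal)$J
  }, numeric(1))
  n_rec <- 48
  # mean of 12 draws of chi2_48 has sd sqrt(2*48/12)
  expect_lt(abs(mean(Js) - n_rec), 3 * sqrt(2 * n_rec / 12))
})

test_that("blow-up regions earn an ordered finite penalty, not an error", {
  s <- make_glv2_problem(0.1)
  # strong positive self-interaction: guaranteed finite-time blow-up
  bad <- c(2, 2, 3, 0, 0, 3)
  w <- wls_cost(s$problem, bad)
  expect_equal(w$status, "blowup_abort")
  expect_true(is.finite(w$J))
  expect_gt(w$J, wls_cost(s$problem, s$fx$theta_nominal)$J)
  # the penalty dominates any feasible objective value
  expect_gt(w$J, sum((s$ds$value / s$ds$sigma)^2))
  # record-order invariance of the cost
  perm <- sample(nrow(s$ds))
  pr2 <- estimation_problem(s$fx$model, s$fx$designs, s$ds[perm, ])
  expect_equal(wls_cost(pr2, s$fx$theta_nominal)$J,
               wls_cost(s$problem, s$fx$theta_nominal)$J, tolerance = 1e-12)
})

test_that("fit classification thresholds the log10 objective ratio", {
  expect_equal(classify_fit(10, 10), "GF")                 # r = 0
  expect_equal(classify_fit(10 * 10^(1), 10, 0.25), "LO")  # r = +1
  expect_equal(classify_fit(10 * 10^(-1), 10, 0.25), "OF") # r = -1
  expect_equal(classify_fit(10^0.2 * 10, 10, 0.25), "GF")  # inside band
  expect_error(classify_fit(1, 0), "positive")
})

test_that("multistart from the truth stays at the global optimum", {
  s <- make_glv2_problem(0, seed = 3)
  ens <- multistart_local(s$problem, n_starts = 1, seed = 1,
                          starts = matrix(s$fx$theta_nominal, 1))
  expect_equal(ens$results[[1]]$status, "converged")
  expect_lt(ens$results[[1]]$J, 1e-6 * nrow(s$ds))
  expect_equal(ens$summary$converged, 1)
})

test_that("multistart discovers distinct local optima of a multimodal fit", {
  # x' = theta^2, x0 = 0, data y(1) = 1: exact fits at theta = +/- 1
  m <- general_model(function(x, th, u, t) th[1]^2, n_x = 1,
                     param_names = "k", bounds = matrix(c(-3, 3), 1, 2))
  om <- observation_map("fo", n_x = 1)
  d <- experiment_design("e1", x0 = 0, t_span = c(0, 1),
                         sampling_times = 1, obs_map = om)
  ds <- tibble::tibble(experiment = "e1", observable = "y1", time = 1,
                       value = 1, sigma = 0.1)
  pr <- estimation_problem(m, list(d), ds)
  ens <- multistart_local(pr, n_starts = 2, seed = 1,
                          starts = matrix(c(-2, 2), 2))
  ests <- vapply(ens$results, function(f) f$theta[[1]], numeric(1))
  expect_equal(sort(ests), c(-1, 1), tolerance = 1e-4)
})

test_that("multistart ensemble fractions are consistent and seed-stable", {
  s <- make_glv2_problem(0.1, seed = 4)
  ens <- multistart_local(s$problem, n_starts = 20, seed = 9)
  g <- glance(ens)
  expect_equal(g$converged + g$blowup + g$solver_failure, 1)
  expect_true(all(purrr::map_lgl(ens$results, function(f) {
    all(f$theta >= s$problem$lower - 1e-9) &&
      all(f$theta <= s$problem$upper + 1e-9)
  })))
  ens2 <- multistart_local(s$problem, n_starts = 20, seed = 9)
  expect_identical(ens$runs, ens2$runs)
})

test_that("scatter search recovers a linear model's least-squares solution", {
  # y = a + b t through x' = b with x0 = a estimated: normal-equations oracle
  m <- general_model(function(x, th, u, t) th[1], n_x = 1,
                     param_names = "slope",
                     bounds = matrix(c(-5, 5), 1, 2))
  om <- observation_map("fo", n_x = 1)
  tt <- c(0.5, 1, 1.5, 2, 3)
  d <- experiment_design("e1", x0 = 0, t_span = c(0, 3),
                         sampling_times = tt, obs_map = om,
                         estimate_x0 = TRUE,
                         x0_bounds = matrix(c(-5, 5), 1, 2))
  y <- c(1.1, 1.6, 1.9, 2.6, 3.4)
  ds <- tibble::tibble(experiment = "e1", observable = "y1", time = tt,
                       value = y, sigma = 1)
  pr <- estimation_problem(m, list(d), ds)
  fit <- ess_optimize(pr, seed = 2,
                      settings = ess_settings(max_evals = 400))
  ls <- unname(coef(lm(y ~ tt)))  # (intercept, slope)
  expect_equal(unname(fit$theta[["slope"]]), ls[2], tolerance = 1e-6)
  expect_equal(unname(fit$theta[["x0_e1_x1"]]), ls[1], tolerance = 1e-6)
})

test_that("scatter search trace is monotone and never worse than the
           initial population", {
  s <- make_glv2_problem(0.1, seed = 6)
  for (sd in 1:3) {
    fit <- ess_optimize(s$problem, seed = sd,
                        settings = ess_settings(max_evals = 600))
    expect_true(all(diff(fit$trace$J_best) <= 1e-12))
    expect_lte(fit$J, fit$trace$J_best[1])
    expect_equal(fit$status, "converged")
  }
})

test_that("both optimizers reach the exact optimum on noise-free data", {
  s <- make_glv2_problem(0, seed = 8)
  n_rec <- nrow(s$ds)
  fit_ess <- ess_optimize(s$problem, seed = 1,
                          settings = ess_settings(max_evals = 1500))
  expect_lt(fit_ess$J, 1e-6 * n_rec)
  ens <- multistart_local(s$problem, n_starts = 15, seed = 2)
  best <- min(ens$runs$J[ens$runs$status == "converged"])
  expect_lt(best, 1e-6 * n_rec)
})
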