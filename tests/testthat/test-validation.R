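test_that("white-noise residuals pass every diagnostic", {
  set.seed(31)
  r <- tibble::tibble(experiment = "e1", observable = "y1",
                      time = seq_len(500), residual = rnorm(500))
  d <- residual_diagnostics(r)
  expect_true(d$computed)
  expect_true(d$flags$mean_pass)
  expect_true(d$flags$autocorrelation_pass)
  expect_true(d$flags$variance_homogeneity_pass)
  expect_false(d$flags$overfit_flag)
  expect_gt(d$stats$qq_correlation, 0.995)
})

test_that("a deterministic trend trips the mean and autocorrelation checks", {
  r <- tibble::tibble(experiment = "e1", observable = "y1",
                      time = seq_len(100),
                      residual = seq(-2, 2, length.out = 100) + 1)
  d <- residual_diagnostics(r)
  expect_false(d$flags$mean_pass)
  expect_false(d$flags$autocorrelation_pass)
})

test_that("too few residuals yield a not-computed result, never a guess", {
  d <- residual_diagnostics(c(0.1, -0.2, 0.3))
  expect_false(d$computed)
  expect_null(d$stats)
})

test_that("shrunken residual variance flags potential overfitting", {
  set.seed(8)
  d <- residual_diagnostics(rnorm(200, 0, 0.4))  # variance 0.16 << 1
  expect_true(d$flags$overfit_flag)
})

test_that("exact normal quantiles give a unit Q-Q correlation", {
  r <- qnorm(ppoints(200))
  d <- residual_diagnostics(r)
  expect_equal(d$stats$qq_correlation, 1, tolerance = 1e-12)
  qq <- qq_points(r)
  expect_equal(qq$theoretical, qq$sample, tolerance = 1e-12)
})

test_that("prediction metrics recover hand-computable cases", {
  obs <- tibble::tibble(experiment = "e", observable = c("y1", "y1", "y2", "y2"),
                        time = c(1, 2, 1, 2), value = c(1, 3, 5, 5),
                        sigma = 1)
  perfect <- dplyr::select(obs, -"sigma")
  pm <- prediction_metrics(perfect, obs)
  expect_equal(pm$RMSE, c(0, 0))
  expect_equal(attr(pm, "rmse_overall"), 0)

  # constant offset c on every point: RMSE = c; constant series flagged
  off <- dplyr::mutate(perfect, value = value + 0.5)
  pm2 <- prediction_metrics(off, obs)
  expect_equal(pm2$RMSE, c(0.5, 0.5))
  expect_true(pm2$nrmse_defined[pm2$observable == "y1"])
  expect_false(pm2$nrmse_defined[pm2$observable == "y2"])  # zero range
  expect_equal(pm2$NRMSE[pm2$observable == "y1"], 0.5 / 2)

  expect_error(prediction_metrics(perfect[1:2, ], obs), "align")
})

test_that("diagnostics are invariant to observable relabeling", {
  set.seed(5)
  r <- tibble::tibble(experiment = rep(c("e1", "e2"), each = 50),
                      observable = rep(c("y1", "y2"), 50),
                      time = rep(1:50, 2), residual = rnorm(100))
  d1 <- residual_diagnostics(r)
  r2 <- dplyr::mutate(r, observable = ifelse(observable == "y1", "b", "a"))
  d2 <- residual_diagnostics(r2)
  expect_equal(d1$stats$qq_correlation, d2$stats$qq_correlation)
  expect_equal(d1$stats$mean_z, d2$stats$mean_z)
  expect_equal(sort(d1$stats$per_series$lag1),
               sort(d2$stats$per_series$lag1))
})

test_that("the true model generalizes exactly on noise-free data", {
  fx <- glv2_fixture()
  ds <- exact_dataset(fx$model, fx$theta_nominal, fx$designs)
  pr <- estimation_problem(fx$model, fx$designs, ds)
  cv <- cross_validate(pr, seed = 3,
                       settings = ess_settings(max_evals = 800))
  expect_equal(nrow(cv$folds), 2)  # leave-one-experiment-out
  expect_true(all(cv$folds$nrmse_val < 1e-4))
})

test_that("cross-validation on noisy data shows optimism", {
  # validation error out-ranks the training-residual scale on average
  fx <- glv2_fixture()
  nrmse_tr <- c(); nrmse_val <- c()
  for (s in 1:3) {
    ds <- generate_dataset(fx$model, fx$theta_nominal, fx$designs,
                           noise_model("proportional", 0.1), seed = 60 + s)
    pr <- estimation_problem(fx$model, fx$designs, ds)
    cv <- cross_validate(pr, seed = s,
                         settings = ess_settings(max_evals = 700))
    # training NRMSE proxy: refit on the training half and score it there
    for (k in seq_len(nrow(cv$folds))) {
      held <- cv$fold_plan[[k]]
      tr_ids <- setdiff(pr$experiments, held)
      m_tr <- mcident:::validate_fit(pr, cv$fits[[k]], tr_ids)
      nrmse_tr <- c(nrmse_tr, m_tr$nrmse)
      nrmse_val <- c(nrmse_val, cv$folds$nrmse_val[k])
    }
  }
  expect_gt(mean(nrmse_val), mean(nrmse_tr))
})

test_that("plausibility rules evaluate ranges, signs and comparisons", {
  th <- c(mu_1 = 1.0, mu_2 = -0.1, beta_1_2 = 0.3, mortality = 0.2)
  rules <- tibble::tibble(
    parameter = c("mu_1", "mu_2", "beta_1_2", "mortality"),
    rule = c("range", "positive", "negative", "less_than"),
    min = c(0.1, NA, NA, NA), max = c(2, NA, NA, NA),
    other = c(NA, NA, NA, "mu_1")
  )
  out <- plausibility_check(th, rules)
  expect_equal(out$verdict,
               c("pass", "violation", "violation", "pass"))
  expect_error(plausibility_check(th, tibble::tibble(parameter = "zzz",
                                                     rule = "positive")),
               "unknown parameter")
})
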