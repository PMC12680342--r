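drift_problem <- function(times = c(1, 2), sigma = 1, values = NULL) {
  m <- drift_model()
  om <- observation_map("fo", n_x = 1)
  d <- experiment_design("e1", x0 = 0, t_span = c(0, max(times)),
                         sampling_times = times, obs_map = om)
  ds <- tibble::tibble(experiment = "e1", observable = "y1", time = times,
                       value = values %||% times, sigma = sigma)
  list(model = m, design = d,
       problem = estimation_problem(m, list(d), ds))
}

test_that("sensitivity of x' = theta is exactly t", {
  pr <- drift_problem(times = c(0.5, 1, 2))$problem
  for (method in c("forward_ode", "finite_difference")) {
    s <- compute_sensitivities(pr, 1, method = method)
    expect_equal(unname(s$S[, 1]), c(0.5, 1, 2), tolerance = 1e-6)
  }
})

test_that("forward and finite-difference sensitivities agree on a community model", {
  fx <- glv2_fixture()
  ds <- generate_dataset(fx$model, fx$theta_nominal, fx$designs,
                         noise_model("proportional", 0.05), seed = 2)
  pr <- estimation_problem(fx$model, fx$designs, ds)
  sf <- compute_sensitivities(pr, fx$theta_nominal, "forward_ode")
  sd_ <- compute_sensitivities(pr, fx$theta_nominal, "finite_difference")
  expect_lt(max(abs(sf$S - sd_$S)) / max(abs(sf$S)), 1e-4)

  # FIM agreement inherits the sensitivity agreement
  f1 <- compute_fim(sf)$fim
  f2 <- compute_fim(sd_)$fim
  expect_lt(max(abs(f1 - f2)) / max(abs(f1)), 1e-3)
})

test_that("a parameter absent from dynamics and observation has zero sensitivity", {
  m <- general_model(function(x, th, u, t) th[1], n_x = 1,
                     param_names = c("k", "unused"),
                     bounds = matrix(c(-5, -5, 5, 5), 2, 2))
  om <- observation_map("fo", n_x = 1)
  d <- experiment_design("e1", x0 = 0, t_span = c(0, 2),
                         sampling_times = c(1, 2), obs_map = om)
  ds <- tibble::tibble(experiment = "e1", observable = "y1",
                       time = c(1, 2), value = c(1, 2), sigma = 1)
  pr <- estimation_problem(m, list(d), ds)
  s <- compute_sensitivities(pr, c(1, 3), method = "forward_ode")
  expect_equal(unname(s$S[, "unused"]), c(0, 0))
})

test_that("scalar FIM equals the sum of squared weighted sensitivities", {
  pr <- drift_problem(times = c(1, 2), sigma = 1)$problem
  s <- compute_sensitivities(pr, 1, "forward_ode")
  fim <- compute_fim(s)
  expect_equal(drop(fim$fim), 5, tolerance = 1e-8)  # 1^2 + 2^2
  expect_false(fim$singular_flag)

  # F is symmetric PSD by construction on a random multiparameter case
  fx <- glv2_fixture()
  ds <- generate_dataset(fx$model, fx$theta_nominal, fx$designs,
                         noise_model("proportional", 0.1), seed = 5)
  prg <- estimation_problem(fx$model, fx$designs, ds)
  F2 <- compute_fim(compute_sensitivities(prg, fx$theta_nominal,
                                          "forward_ode"))
  expect_equal(F2$fim, t(F2$fim), tolerance = 1e-10)
  expect_true(all(F2$eigenvalues > -1e-8 * max(F2$eigenvalues)))
})

test_that("perfect parameter collinearity yields a singular FIM", {
  m <- collinear_model()
  om <- observation_map("fo", n_x = 1)
  d <- experiment_design("e1", x0 = 0, t_span = c(0, 2),
                         sampling_times = c(0.5, 1, 2), obs_map = om)
  ds <- tibble::tibble(experiment = "e1", observable = "y1",
                       time = c(0.5, 1, 2), value = c(1, 2, 4), sigma = 1)
  pr <- estimation_problem(m, list(d), ds)
  fim <- compute_fim(compute_sensitivities(pr, c(1, 1), "forward_ode"))
  expect_true(fim$singular_flag)
  ev <- fim$eigenvalues
  expect_lt(min(ev) / max(ev), 1e-10)
})

test_that("Cramer-Rao half-widths follow the closed form and sigma scaling", {
  pr <- drift_problem(times = c(1, 2), sigma = 1)$problem
  fim <- compute_fim(compute_sensitivities(pr, 1, "forward_ode"))
  cr <- cramer_rao_intervals(fim, 1, confidence = 0.95)
  expect_equal(unname(cr$ci$half_width), qnorm(0.975) * sqrt(1 / 5),
               tolerance = 1e-8)
  expect_equal(unname(diag(cr$correlation)), 1)

  # doubling every sigma doubles every half-width (F scales as 1/sigma^2)
  pr2 <- drift_problem(times = c(1, 2), sigma = 2)$problem
  fim2 <- compute_fim(compute_sensitivities(pr2, 1, "forward_ode"))
  cr2 <- cramer_rao_intervals(fim2, 1)
  expect_equal(cr2$ci$half_width, 2 * cr$ci$half_width, tolerance = 1e-8)
})

test_that("Cramer-Rao bound matches the Monte-Carlo estimator spread", {
  # linear-Gaussian toy y = theta * t + eps: the least-squares estimator is
  # exactly Gaussian with sd = sigma / sqrt(sum t^2); CR is tight here
  tt <- c(0.5, 1, 1.5, 2)
  sigma <- 0.3
  pr <- drift_problem(times = tt, sigma = sigma)$problem
  fim <- compute_fim(compute_sensitivities(pr, 1, "forward_ode"))
  cr_sd <- cramer_rao_intervals(fim, 1)$ci$sd
  n_rep <- 10000
  set.seed(99)
  # closed-form LS estimator over 1e4 simulated replicates
  est <- vapply(seq_len(n_rep), function(i) {
    y <- tt + rnorm(length(tt), 0, sigma)
    sum(tt * y) / sum(tt^2)
  }, numeric(1))
  mc_sd <- sd(est)
  mc_se <- mc_sd / sqrt(2 * (n_rep - 1))
  expect_lt(abs(cr_sd - mc_sd), 3 * mc_se)
})

test_that("full observation is locally identifiable; aggregation loses rank", {
  fx2 <- glv2_fixture(); fx3 <- glv3_fixture()
  expect_equal(local_sia_rank(fx2$model, observation_map("fo", n_x = 2),
                              seed = 3)$verdict, "locally_identifiable")
  expect_equal(local_sia_rank(fx3$model, observation_map("fo", n_x = 3),
                              seed = 3)$verdict, "locally_identifiable")

  # single-species observation with unknown initial conditions: the hidden
  # species' scale is free (x2 -> c x2 compensated by beta rescaling)
  r_sub <- local_sia_rank(fx2$model,
                          observation_map("po_subset", n_x = 2, indices = 1),
                          estimate_x0 = TRUE, seed = 3)
  expect_equal(r_sub$verdict, "locally_non_identifiable")
  expect_gte(r_sub$deficiency, 1)
  expect_equal(nrow(r_sub$implicated), r_sub$n_free)

  # total biomass of three species with unknown initial conditions
  r_sum3 <- local_sia_rank(fx3$model,
                           observation_map("po_sum", n_x = 3, indices = 1:3),
                           estimate_x0 = TRUE, seed = 3)
  expect_equal(r_sum3$verdict, "locally_non_identifiable")
})

noise_free_records_probe <- function(fx) {
  om <- observation_map("po_sum", n_x = 2, indices = 1:2)
  d <- experiment_design("sia", x0 = c(0.1, 0.1), t_span = c(0, 10),
                         sampling_times = seq(0.1, 10, length.out = 40),
                         obs_map = om, estimate_x0 = c(TRUE, TRUE),
                         x0_bounds = matrix(rep(c(1e-4, 10), each = 2), 2, 2))
  ds <- exact_dataset(fx$model, fx$theta_nominal, d)
  pr <- estimation_problem(fx$model, list(d), ds)
  compute_sensitivities(pr, c(fx$theta_nominal, d$x0), "forward_ode")
}

test_that("two-species total biomass is the local/global gap case", {
  # the aggregate scheme that global differential-algebra analysis calls
  # non-identifiable is locally full rank here, but extremely
  # ill-conditioned: local analysis can only certify the necessary
  # condition, and the near-null direction is the practical symptom
  fx <- glv2_fixture()
  r <- local_sia_rank(fx$model,
                      observation_map("po_sum", n_x = 2, indices = 1:2),
                      estimate_x0 = TRUE, seed = 3)
  expect_equal(r$deficiency, 0)
  ds <- noise_free_records_probe(fx)
  sv <- svd(ds$S)$d
  expect_lt(min(sv) / max(sv), 1e-4)  # near-singular identifiability matrix
})

test_that("collinear parameters implicate the (1,-1) direction", {
  m <- collinear_model()
  om <- observation_map("fo", n_x = 1)
  d <- experiment_design("e1", x0 = 0, t_span = c(0, 5),
                         sampling_times = seq(0.5, 5, 0.5), obs_map = om)
  r <- local_sia_rank(m, om, design = d, theta_probe = c(1, 1), n_probes = 3,
                      seed = 1)
  expect_equal(r$rank, 1)
  expect_equal(r$deficiency, 1)
  dir <- unname(r$implicated[, 1])
  expect_equal(abs(dir), rep(1 / sqrt(2), 2), tolerance = 1e-6)
  expect_equal(sum(dir), 0, tolerance = 1e-6)
})

test_that("the rank verdict is invariant to rescaling the time units", {
  fx <- glv2_fixture()
  m <- fx$model
  # same dynamics with time in 'minutes': all rates scaled by 1/60
  om <- observation_map("fo", n_x = 2)
  d_fast <- experiment_design("e", x0 = c(0.1, 0.1), t_span = c(0, 10),
                              sampling_times = seq(0.5, 10, length.out = 20),
                              obs_map = om)
  d_slow <- experiment_design("e", x0 = c(0.1, 0.1), t_span = c(0, 600),
                              sampling_times = seq(30, 600, length.out = 20),
                              obs_map = om)
  r_fast <- local_sia_rank(m, om, design = d_fast,
                           theta_probe = fx$theta_nominal, n_probes = 1)
  m_slow <- glv_model(c(1, 0.8) / 60,
                      matrix(c(-1, -0.4, -0.3, -0.8), 2, byrow = TRUE) / 60,
                      bounds = list(mu = c(0, 2), beta = c(-3, 3)))
  r_slow <- local_sia_rank(m_slow, om, design = d_slow,
                           theta_probe = m_slow$nominal_theta, n_probes = 1)
  expect_equal(r_fast$verdict, r_slow$verdict)
  expect_equal(r_fast$rank, r_slow$rank)
})

test_that("sign agreement counts matching signs with a dead band", {
  th <- c(a = 1, b = -2, c = 0.5, d = -0.1)
  expect_equal(sign_agreement(th, th)$agreement, 1)
  expect_equal(sign_agreement(-th, th)$agreement, 0)
  half <- c(a = 1, b = -2, c = -0.5, d = 0.1)
  expect_equal(sign_agreement(half, th)$agreement, 0.5)
  # zero nominal compared within the dead band
  expect_equal(sign_agreement(c(x = 1e-12), c(x = 0))$agreement, 1)
  expect_equal(sign_agreement(c(x = 0.2), c(x = 0))$agreement, 0)
  expect_error(sign_agreement(1:2, 1:3), "length")
  # subset masking restricts the comparison
  sa <- sign_agreement(half, th, subset = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sa$agreement, 1)
})
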