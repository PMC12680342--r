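# shared toy models and small builders used across the test files

`%||%` <- function(a, b) if (is.null(a)) b else a

logistic_model <- function() glv_model(1, matrix(-1, 1, 1))

# x' = theta (pure drift), y = x: sensitivity S(t) = t exactly
drift_model <- function(nominal = 1) {
  general_model(function(x, th, u, t) th[1], n_x = 1, param_names = "k",
                bounds = matrix(c(-5, 5), 1, 2), nominal_theta = nominal)
}

# y = (theta1 + theta2) * t via x' = theta1 + theta2: perfectly collinear
collinear_model <- function() {
  general_model(function(x, th, u, t) th[1] + th[2], n_x = 1,
                param_names = c("a", "b"),
                bounds = matrix(c(-5, -5, 5, 5), 2, 2),
                nominal_theta = c(1, 1))
}

fo_design <- function(id, x0, tf, n_pts, n_x, t0 = 0) {
  experiment_design(id, x0 = x0, t_span = c(t0, tf),
                    sampling_times = seq(t0 + (tf - t0) / n_pts, tf,
                                         length.out = n_pts),
                    obs_map = observation_map("fo", n_x = n_x))
}

# exact noise-free dataset for a model/design at theta (sigma = 1)
exact_dataset <- function(model, theta, designs) {
  if (inherits(designs, "mc_design")) designs <- list(designs)
  generate_dataset(model, theta, designs, noise_model("proportional", 0),
                   seed = 1)
}
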