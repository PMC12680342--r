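#' Residual diagnostics for a calibrated model
#'
#' Under a well-specified model with Gaussian errors the standardized
#' residuals behave like white noise: approximately zero-mean,
#' uncorrelated, of unit variance, and normal. The diagnostics computed
#' are a zero-mean z test (known unit variance under the model), the
#' lag-1 autocorrelation of each time-ordered `(experiment, observable)`
#' series, the variance ratio between the first and second half of each
#' series, and the quantile-quantile correlation between the sorted
#' residuals and standard-normal quantiles. An empirical residual
#' variance materially below one with high Q-Q correlation suggests the
#' fit is absorbing noise; variance below `overfit_var_threshold` flags
#' potential overfitting (an explicit, configurable operationalization of
#' the Q-Q indicator). Groups with fewer than `min_n` residuals are
#' marked not computed, never guessed.
#'
#' @param residuals Either a numeric vector of standardized residuals or
#'   a tibble with columns `experiment`, `observable`, `time`,
#'   `residual`.
#' @param min_n Minimum residuals required per diagnostic group
#'   (default 8).
#' @param overfit_var_threshold Variance level below which potential
#'   overfitting is flagged (default 0.5).
#' @return An `mc_residual_diagnostics` list: `computed`, `stats` (mean,
#'   `mean_z`, `variance`, `qq_correlation`, per-series lag-1
#'   autocorrelations and variance ratios), and pass/fail `flags`
#'   (thresholds: `|mean z| < 2`, `|lag-1 ac| < 2/sqrt(n)`, variance
#'   ratio in `[0.5, 2]`).
#' @export
residual_diagnostics <- function(residuals, min_n = 8,
                                 overfit_var_threshold = 0.5) {
  if (is.numeric(residuals)) {
    residuals <- tibble(experiment = "e1", observable = "y1",
                        time = seq_along(residuals),
                        residual = as.numeric(residuals))
  }
  stopifnot(all(c("experiment", "observable", "time", "residual")
                %in% names(residuals)))
  r_all <- residuals$residual
  n <- length(r_all)
  if (n < min_n) {
    return(structure(list(computed = FALSE, n = n, stats = NULL,
                          flags = NULL),
                     class = "mc_residual_diagnostics"))
  }
  mean_z <- mean(r_all) * sqrt(n)  # one-sample z, unit variance under model
  qq <- stats::cor(sort(r_all), stats::qnorm(stats::ppoints(n)))

  per_series <- residuals |>
    dplyr::arrange(.data$experiment, .data$observable, .data$time) |>
    dplyr::group_by(.data$experiment, .data$observable) |>
    dplyr::summarise(
      n_s = dplyr::n(),
      lag1 = if (dplyr::n() >= min_n)
        stats::cor(.data$residual[-dplyr::n()], .data$residual[-1])
        else NA_real_,
      var_ratio = if (dplyr::n() >= min_n) {
        h <- floor(dplyr::n() / 2)
        stats::var(.data$residual[seq_len(h)]) /
          stats::var(.data$residual[(h + 1):dplyr::n()])
      } else NA_real_,
      .groups = "drop"
    )
  lag1_thresh <- 2 / sqrt(per_series$n_s)
  flags <- list(
    mean_pass = abs(mean_z) < 2,
    autocorrelation_pass = all(abs(per_series$lag1) < lag1_thresh,
                               na.rm = TRUE),
    variance_homogeneity_pass = all(per_series$var_ratio >= 0.5 &
                                    per_series$var_ratio <= 2, na.rm = TRUE),
    overfit_flag = stats::var(r_all) < overfit_var_threshold
  )
  structure(
    list(computed = TRUE, n = n,
         stats = list(mean = mean(r_all), mean_z = mean_z,
                      variance = stats::var(r_all), qq_correlation = qq,
                      per_series = per_series),
         flags = flags),
    class = "mc_residual_diagnostics"
  )
}

#' @export
print.mc_residual_diagnostics <- function(x, ...) {
  if (!x$computed) {
    cat("<mc_residual_diagnostics> not computed (too few residuals)\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<mc_residual_diagnostics> n=%d | mean z=%.2f | ",
                     "var=%.3f | qq=%.4f%s\n"),
              x$n, x$stats$mean_z, x$stats$variance,
              x$stats$qq_correlation,
              if (x$flags$overfit_flag) " [possible overfit]" else ""))
  invisible(x)
}

#' Prediction accuracy metrics on validation data
#'
#' Root-mean-squared error per observable plus its normalized form,
#' `NRMSE = RMSE / (max - min)` of the observed values for that
#' observable. A constant observed series has no range and its NRMSE is
#' flagged undefined rather than reported. The overall values are
#' record-weighted.
#'
#' @param predicted Tibble with columns `experiment`, `observable`,
#'   `time`, `value` (model predictions at the validation times).
#' @param observed Validation dataset (same columns; the `value` column
#'   holds the measurements).
#' @return An `mc_prediction_metrics` tibble (one row per observable:
#'   `RMSE`, `NRMSE`, `nrmse_defined`) with attributes `rmse_overall`
#'   and `nrmse_overall`.
#' @export
prediction_metrics <- function(predicted, observed) {
  jn <- dplyr::inner_join(
    as_tibble(observed),
    dplyr::rename(as_tibble(predicted), pred = "value"),
    by = c("experiment", "observable", "time")
  )
  if (nrow(jn) != nrow(as_tibble(observed))) {
    abort("prediction times do not align with the validation records")
  }
  per_obs <- jn |>
    dplyr::group_by(.data$observable) |>
    dplyr::summarise(
      n = dplyr::n(),
      RMSE = sqrt(mean((.data$value - .data$pred)^2)),
      range = max(.data$value) - min(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      nrmse_defined = .data$range > 0,
      NRMSE = ifelse(.data$nrmse_defined, .data$RMSE / .data$range, NA_real_)
    ) |>
    dplyr::select("observable", "n", "RMSE", "NRMSE", "nrmse_defined")
  rmse_overall <- sqrt(mean((jn$value - jn$pred)^2))
  def <- per_obs[per_obs$nrmse_defined, , drop = FALSE]
  nrmse_overall <- if (nrow(def)) sum(def$NRMSE * def$n) / sum(def$n)
                   else NA_real_
  structure(per_obs, rmse_overall = rmse_overall,
            nrmse_overall = nrmse_overall,
            class = c("mc_prediction_metrics", class(per_obs)))
}

#' Cross-validate a calibration on held-out experiments
#'
#' For each fold the model is re-calibrated on the training experiments
#' only and its predictions are scored against the held-out validation
#' experiments — the decisive test for overfitting, since a solution that
#' fits noise generalizes poorly to new initial conditions. The default
#' fold plan is leave-one-experiment-out.
#'
#' @param problem An [estimation_problem()] holding all experiments.
#' @param fold_plan List of character vectors, each the experiment ids
#'   held out in one fold; `NULL` for leave-one-experiment-out.
#' @param seed Integer master seed; fold seeds derive from it.
#' @param optimizer `"ess"` (default) or `"multistart"`.
#' @param settings [ess_settings()] for the refits (or `n_starts` for
#'   multistart via `ms_starts`).
#' @param ms_starts Number of starts when `optimizer = "multistart"`.
#' @param delta Good-fit classification half-width.
#' @return An `mc_validation_report`: per-fold tibble (`fold`,
#'   `held_out`, `J_train`, `rmse_val`, `nrmse_val`, `status`,
#'   `classification`), aggregate means, and the per-fold fits.
#' @export
cross_validate <- function(problem, fold_plan = NULL, seed = 1,
                           optimizer = c("ess", "multistart"),
                           settings = ess_settings(), ms_starts = 20,
                           delta = 0.25) {
  optimizer <- match.arg(optimizer)
  ids <- problem$experiments
  fold_plan <- fold_plan %||% purrr::map(ids, identity)
  if (any(lengths(fold_plan) == 0)) abort("empty fold in fold plan")
  full_designs <- problem$designs
  dataset <- problem$dataset

  fits <- list()
  rows <- purrr::imap(fold_plan, function(held, k) {
    held <- as.character(held)
    sp <- split_dataset(dataset, held)
    if (nrow(sp$training) == 0) abort(sprintf("fold %d has an empty training set", k))
    train_problem <- estimation_problem(
      problem$model, full_designs[unique(sp$training$experiment)],
      sp$training, rtol = problem$rtol, atol = problem$atol,
      guard_threshold = problem$guard_threshold
    )
    fit <- if (optimizer == "ess") {
      ess_optimize(train_problem, seed = seed + 101L * k,
                   settings = settings, delta = delta)
    } else {
      ens <- multistart_local(train_problem, n_starts = ms_starts,
                              seed = seed + 101L * k, delta = delta)
      best_converged_fit(ens)
    }
    fits[[k]] <<- fit
    val_metrics <- validate_fit(problem, fit, held)
    tibble(fold = k, held_out = paste(held, collapse = "+"),
           J_train = fit$J, status = fit$status,
           classification = fit$classification,
           rmse_val = val_metrics$rmse, nrmse_val = val_metrics$nrmse)
  })
  folds <- dplyr::bind_rows(rows)
  structure(
    list(folds = folds,
         aggregate = list(mean_rmse = mean(folds$rmse_val, na.rm = TRUE),
                          mean_nrmse = mean(folds$nrmse_val, na.rm = TRUE)),
         fits = fits, fold_plan = fold_plan),
    class = "mc_validation_report"
  )
}

best_converged_fit <- function(ensemble) {
  ok <- purrr::keep(ensemble$results, ~ .x$status == "converged")
  if (length(ok) == 0) return(ensemble$results[[which.min(
    purrr::map_dbl(ensemble$results, "J"))]])
  ok[[which.min(purrr::map_dbl(ok, "J"))]]
}

# score a fitted parameter vector on held-out experiments of the full
# problem; model parameters only (held-out x0 are taken from the designs).
# When the validation simulation diverges, the prediction at unreached
# times is scored at the blow-up guard magnitude: a model that predicts
# divergence earns a huge but finite (hence comparable) error.
validate_fit <- function(problem, fit, held_out) {
  theta <- fit$theta[seq_len(problem$model$n_theta)]
  obs <- problem$dataset[problem$dataset$experiment %in% held_out, ,
                         drop = FALSE]
  preds <- purrr::map(held_out, function(e) {
    d <- problem$designs[[e]]
    pr <- predict_observables(problem$model, theta, d,
                              rtol = problem$rtol, atol = problem$atol,
                              guard_threshold = problem$guard_threshold)
    if (pr$status == "ok") {
      return(dplyr::mutate(pr$predictions, experiment = e))
    }
    # divergence: real predictions up to t_stop, guard magnitude beyond
    guard <- problem$guard_threshold %||% (1e6 * max(1, max(abs(d$x0))))
    times <- sort(unique(c(d$t_span[1], unlist(d$sampling_times))))
    tr <- simulate_model(problem$model, theta, x0 = d$x0, times = times,
                         rtol = problem$rtol, atol = problem$atol,
                         guard_threshold = problem$guard_threshold)
    t_stop <- trajectory_t_stop(tr)
    om <- d$obs_map
    X <- as.matrix(tr[, -1, drop = FALSE])
    rows <- purrr::imap(d$sampling_times, function(ts, obs_name) {
      o_idx <- match(obs_name, om$obs_names)
      y <- vapply(ts, function(tk) {
        r <- match(tk, tr$time)
        if (tk <= t_stop && !is.na(r) && all(is.finite(X[r, ]))) {
          min(max(om$g(X[r, ], tk)[o_idx], -guard), guard)
        } else guard
      }, numeric(1))
      tibble(observable = obs_name, time = ts, value = y, experiment = e)
    })
    dplyr::bind_rows(rows)
  })
  pm <- prediction_metrics(dplyr::bind_rows(preds), obs)
  list(rmse = attr(pm, "rmse_overall"), nrmse = attr(pm, "nrmse_overall"))
}

#' Mechanistic plausibility checks on parameter estimates
#'
#' Evaluates domain rules against named estimates: `"range"` (value in
#' `[min, max]`, e.g. maximum specific growth rates within 0.1-2 per
#' hour for many bacteria), `"positive"`, `"negative"` (sign
#' expectations for interaction coefficients: negative for competition
#' or inhibition, positive for facilitation or cross-feeding), and
#' `"less_than"` (comparative rules such as mortality below growth).
#'
#' @param theta_hat Named parameter estimates.
#' @param rules A tibble (or list of lists coercible to one) with
#'   columns `parameter`, `rule` and, as needed, `min`, `max`, `other`.
#' @return A tibble with `parameter`, `rule`, `value`, `verdict`
#'   (`"pass"` / `"violation"`).
#' @export
plausibility_check <- function(theta_hat, rules) {
  if (!is.data.frame(rules)) rules <- dplyr::bind_rows(rules)
  stopifnot(all(c("parameter", "rule") %in% names(rules)))
  nm <- names(theta_hat)
  if (is.null(nm)) abort("theta_hat must be named")
  unknown <- setdiff(rules$parameter, nm)
  if (length(unknown)) {
    abort(sprintf("rule references unknown parameter(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  rows <- purrr::pmap(rules, function(parameter, rule, ...) {
    extra <- list(...)
    v <- as.numeric(theta_hat[[parameter]])
    ok <- switch(rule,
      range = v >= extra$min && v <= extra$max,
      positive = v > 0,
      negative = v < 0,
      less_than = v < as.numeric(theta_hat[[extra$other]]),
      abort(sprintf("unknown rule '%s'", rule))
    )
    tibble(parameter = parameter, rule = rule, value = v,
           verdict = if (ok) "pass" else "violation")
  })
  dplyr::bind_rows(rows)
}
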