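#' Validate a workflow run configuration
#'
#' Checks the configuration for [run_workflow()]; violations raise an
#' error naming the offending field. Every default left open by the
#' configuration is materialized into the returned list, so stored run
#' configurations are self-describing.
#'
#' @param config A list, or a path to a JSON file holding one.
#' @return The completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort("config must be a list or JSON path")
  req <- function(field, check, what) {
    v <- config[[field]]
    if (is.null(v) || !check(v)) {
      abort(sprintf("config field '%s' %s", field,
                    if (is.null(v)) "is missing" else paste("must be", what)))
    }
    v
  }
  req("fixture", is.character, "a fixture name")
  get_fixture(config$fixture)  # errors on unknown name
  req("seed", function(s) is.numeric(s) && s == round(s), "an integer seed")

  config$synthesis <- utils::modifyList(
    list(noise_kind = "proportional", noise_level = 0.1), config$synthesis %||% list())
  if (!is.null(config$dataset) && !file.exists(config$dataset)) {
    abort("config field 'dataset' points to a missing file")
  }
  config$phases <- utils::modifyList(
    list(sia = TRUE, estimation = TRUE, pia = TRUE, stability = TRUE,
         validation = TRUE),
    config$phases %||% list()
  )
  config$optimizer <- utils::modifyList(
    list(method = "ess", max_evals = NULL, n_starts = 50,
         local_max_iter = 100), config$optimizer %||% list())
  if (!config$optimizer$method %in% c("ess", "multistart")) {
    abort("config field 'optimizer$method' must be 'ess' or 'multistart'")
  }
  config$thresholds <- utils::modifyList(
    list(delta = 0.25, eps_stab = 1e-8, rank_tol = 1e-8, ci_level = 0.95,
         horizon_factor = 3), config$thresholds %||% list())
  for (nm in names(config$thresholds)) {
    v <- config$thresholds[[nm]]
    if (!is.numeric(v) || v <= 0) {
      abort(sprintf("config field 'thresholds$%s' must be positive", nm))
    }
  }
  config
}

#' Run the three-phase identification workflow
#'
#' Executes, from a single configuration: Phase 1, the local
#' structural-identifiability rank screen for the fully-observed scheme
#' (and the partial-observation schemes when requested); Phase 2, global
#' or multistart calibration, practical identifiability (FIM, Cramer-Rao
#' intervals, correlations) and the long-horizon stability screen;
#' Phase 3, residual diagnostics, leave-one-experiment-out
#' cross-validation and optional plausibility rules. All randomness
#' derives from the master seed, so identical configurations give
#' identical numeric results.
#'
#' @param config A configuration list or JSON path (see
#'   [validate_config()]): at minimum `fixture` and `seed`.
#' @param out_dir Optional directory; phase outputs are written there as
#'   JSON plus a consolidated markdown report.
#' @return A list with elements `config`, `sia`, `fit`, `pia`,
#'   `stability`, `validation` and `verdict`.
#' @export
run_workflow <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  fx <- get_fixture(config$fixture)
  seed <- as.integer(config$seed)
  th <- config$thresholds

  dataset <- if (!is.null(config$dataset)) {
    read_dataset(config$dataset)
  } else {
    generate_dataset(fx$model, fx$theta_nominal, fx$designs,
                     noise_model(config$synthesis$noise_kind,
                                 config$synthesis$noise_level),
                     seed = seed + 1L)
  }
  problem <- estimation_problem(fx$model, fx$designs, dataset)

  out <- list(config = config)

  if (isTRUE(config$phases$sia)) {
    om_fo <- observation_map("fo", n_x = fx$model$n_x)
    out$sia <- local_sia_rank(fx$model, om_fo, x0 = fx$designs[[1]]$x0,
                              seed = seed + 2L, rank_tol = th$rank_tol)
    if (out$sia$verdict != "locally_identifiable") {
      warn("full-observation scheme is locally non-identifiable; consider reparameterization")
    }
  }

  if (isTRUE(config$phases$estimation)) {
    opt <- config$optimizer
    out$fit <- if (opt$method == "ess") {
      ess_optimize(problem, seed = seed + 3L,
                   settings = ess_settings(max_evals = opt$max_evals,
                                           local_max_iter = opt$local_max_iter),
                   delta = th$delta)
    } else {
      best_converged_fit(multistart_local(problem, n_starts = opt$n_starts,
                                          seed = seed + 3L, delta = th$delta))
    }
  }

  if (isTRUE(config$phases$pia)) {
    if (is.null(out$fit)) abort("practical identifiability requires a fit; enable the estimation phase")
    sens <- compute_sensitivities(problem, out$fit$theta, method = "forward_ode")
    fim <- compute_fim(sens)
    out$pia <- cramer_rao_intervals(fim, out$fit$theta,
                                    confidence = th$ci_level)
  }

  if (isTRUE(config$phases$stability)) {
    if (is.null(out$fit)) abort("stability screening requires a fit; enable the estimation phase")
    out$stability <- stability_screen(out$fit, problem,
                                      horizon_factor = th$horizon_factor)
  }

  if (isTRUE(config$phases$validation)) {
    if (is.null(out$fit)) abort("validation requires a fit; enable the estimation phase")
    w <- wls_cost(problem, out$fit$theta)
    resid_tb <- dplyr::mutate(
      problem$dataset[, c("experiment", "observable", "time")],
      residual = if (w$status == "ok") w$residuals else NA_real_)
    out$residuals <- residual_diagnostics(resid_tb)
    if (length(problem$experiments) >= 2) {
      cv_settings <- ess_settings(
        max_evals = config$optimizer$max_evals,
        local_max_iter = config$optimizer$local_max_iter)
      out$validation <- cross_validate(problem, seed = seed + 4L,
                                       optimizer = config$optimizer$method,
                                       settings = cv_settings,
                                       ms_starts = config$optimizer$n_starts,
                                       delta = th$delta)
    }
    if (!is.null(config$plausibility_rules)) {
      out$plausibility <- plausibility_check(out$fit$theta,
                                             config$plausibility_rules)
    }
  }

  out$verdict <- workflow_verdict(out)
  if (!is.null(out_dir)) write_workflow_reports(out, out_dir)
  out
}

workflow_verdict <- function(out) {
  parts <- character(0)
  if (!is.null(out$sia)) {
    parts <- c(parts, sprintf("SIA (full observation): %s", out$sia$verdict))
  }
  if (!is.null(out$fit)) {
    parts <- c(parts, sprintf("fit: status=%s, J=%.4g, class=%s",
                              out$fit$status, out$fit$J,
                              out$fit$classification))
  }
  if (!is.null(out$pia)) {
    parts <- c(parts, sprintf("PIA: %d practically non-identifiable parameter(s)",
                              length(out$pia$non_identifiable)))
  }
  if (!is.null(out$stability)) {
    parts <- c(parts, sprintf("stability: %s", out$stability$verdict))
  }
  if (!is.null(out$validation)) {
    parts <- c(parts, sprintf("cross-validation mean NRMSE: %.4g",
                              out$validation$aggregate$mean_nrmse))
  }
  paste(parts, collapse = "; ")
}

write_workflow_reports <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, force = TRUE, pretty = TRUE)
  }
  if (!is.null(out$sia)) js(glance(out$sia), "phase1_sia.json")
  if (!is.null(out$fit)) {
    js(list(glance = glance(out$fit), parameters = tidy(out$fit)),
       "phase2_fit.json")
  }
  if (!is.null(out$pia)) {
    js(list(glance = glance(out$pia), intervals = out$pia$ci,
            non_identifiable = out$pia$non_identifiable), "phase2_pia.json")
    utils::write.csv(out$pia$correlation,
                     file.path(out_dir, "phase2_correlation.csv"))
  }
  if (!is.null(out$stability)) {
    js(list(verdict = out$stability$verdict,
            evidence = out$stability$evidence), "phase2_stability.json")
  }
  if (!is.null(out$validation)) {
    js(list(folds = out$validation$folds,
            aggregate = out$validation$aggregate), "phase3_validation.json")
  }
  md <- c(
    "# Identification workflow report", "",
    sprintf("- fixture: %s", out$config$fixture),
    sprintf("- master seed: %d", out$config$seed), "",
    "## Phase 1: structural identifiability (local rank screen)", "",
    if (!is.null(out$sia)) {
      sprintf("Scheme %s: rank %d of %d free parameters -> %s.",
              out$sia$scheme, out$sia$rank, out$sia$n_free, out$sia$verdict)
    } else "Skipped.", "",
    "## Phase 2: calibration, practical identifiability, stability", "",
    if (!is.null(out$fit)) {
      sprintf("Best fit: J = %.6g (%s, class %s, %d objective evaluations).",
              out$fit$J, out$fit$status, out$fit$classification,
              out$fit$n_obj_evals)
    } else "Skipped.",
    if (!is.null(out$pia)) {
      sprintf("FIM condition number %.3g; flagged parameters: %s.",
              out$pia$condition_number,
              if (length(out$pia$non_identifiable))
                paste(out$pia$non_identifiable, collapse = ", ")
              else "none")
    },
    if (!is.null(out$stability)) {
      sprintf("Stability screen: %s.", out$stability$verdict)
    }, "",
    "## Phase 3: predictive power", "",
    if (!is.null(out$residuals) && out$residuals$computed) {
      sprintf("Residuals: mean z %.2f, variance %.3f, Q-Q correlation %.4f.",
              out$residuals$stats$mean_z, out$residuals$stats$variance,
              out$residuals$stats$qq_correlation)
    },
    if (!is.null(out$validation)) {
      sprintf("Cross-validation: mean RMSE %.4g, mean NRMSE %.4g over %d fold(s).",
              out$validation$aggregate$mean_rmse,
              out$validation$aggregate$mean_nrmse,
              nrow(out$validation$folds))
    }, "",
    "## Verdict", "", out$verdict, ""
  )
  writeLines(unlist(md[!vapply(md, is.null, logical(1))]),
             file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Benchmark optimizer behaviour across case studies
#'
#' The machine behind the calibration statistics: for each case (fixture
#' plus noise level) it generates a synthetic dataset, runs a multistart
#' local ensemble and a set of seeded eSS runs, and tabulates the
#' converged / blow-up / OF / GF / LO fractions.
#'
#' @param cases A list of case lists with fields `fixture`,
#'   `noise_level`, `n_multistart`, `n_ess` and optionally
#'   `ess_max_evals`, `experiments` (design indices to use).
#' @param seed Master seed.
#' @param delta Good-fit half-width for classification.
#' @return A tibble with one row per case and the ensemble fractions.
#' @export
benchmark_suite <- function(cases, seed = 1, delta = 0.25) {
  rows <- purrr::imap(cases, function(case, k) {
    fx <- get_fixture(case$fixture)
    designs <- fx$designs
    if (!is.null(case$experiments)) designs <- designs[case$experiments]
    noise <- noise_model("proportional", case$noise_level %||% 0.1)
    dataset <- generate_dataset(fx$model, fx$theta_nominal, designs, noise,
                                seed = seed + 977L * k)
    problem <- estimation_problem(fx$model, designs, dataset)
    row <- tibble(case = fx$name, noise_level = noise$level)
    if ((case$n_multistart %||% 0) > 0) {
      ens <- multistart_local(problem, n_starts = case$n_multistart,
                              seed = seed + 977L * k + 1L, delta = delta)
      g <- glance(ens)
      row <- dplyr::bind_cols(row, dplyr::rename_with(
        g[, c("converged", "blowup", "solver_failure", "OF", "GF", "LO")],
        ~ paste0("ms_", .x)))
      row$ms_n <- case$n_multistart
    }
    if ((case$n_ess %||% 0) > 0) {
      fits <- purrr::map(seq_len(case$n_ess), function(r) {
        ess_optimize(problem, seed = seed + 977L * k + 10L + r,
                     settings = ess_settings(max_evals = case$ess_max_evals),
                     delta = delta)
      })
      st <- purrr::map_chr(fits, "status")
      cl <- purrr::map_chr(fits, "classification")
      row$ess_n <- case$n_ess
      row$ess_converged <- mean(st == "converged")
      row$ess_GF <- mean(cl == "GF", na.rm = TRUE)
    }
    row
  })
  dplyr::bind_rows(rows)
}
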