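#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a calibrated fit
#'
#' @param x An `mc_fit` from [ess_optimize()] or an ensemble's results.
#' @param ... Unused.
#' @return A tibble with one row per free parameter (`parameter`,
#'   `estimate`).
#' @export
tidy.mc_fit <- function(x, ...) {
  tibble(parameter = names(x$theta) %||% paste0("theta_", seq_along(x$theta)),
         estimate = as.numeric(x$theta))
}

#' @rdname tidy.mc_fit
#' @return `glance()` returns a one-row tibble with the objective value,
#'   status, OF/GF/LO class, evaluation count and seed.
#' @export
glance.mc_fit <- function(x, ...) {
  tibble(J = x$J, status = x$status, classification = x$classification,
         n_obj_evals = x$n_obj_evals, seed = x$seed,
         budget_exhausted = x$budget_exhausted)
}

#' Tidy a multistart / eSS ensemble
#'
#' @param x An `mc_fit_ensemble`.
#' @param ... Unused.
#' @return The per-run tibble (`run`, `J`, `status`, `classification`).
#' @export
tidy.mc_fit_ensemble <- function(x, ...) x$runs

#' @rdname tidy.mc_fit_ensemble
#' @return `glance()` returns the summary fractions as a one-row tibble.
#' @export
glance.mc_fit_ensemble <- function(x, ...) {
  s <- x$summary
  tibble(n_runs = s$n_runs, converged = s$converged, blowup = s$blowup,
         solver_failure = s$solver_failure, OF = s$OF, GF = s$GF, LO = s$LO,
         delta = s$delta,
         J_nominal = s$J_nominal %||% NA_real_)
}

#' Tidy a practical-identifiability report
#'
#' @param x An `mc_fim_report` (after [cramer_rao_intervals()] for the
#'   interval columns).
#' @param ... Unused.
#' @return Per-parameter tibble of estimates, standard errors and
#'   confidence half-widths (when filled in), else the eigenvalue table.
#' @export
tidy.mc_fim_report <- function(x, ...) {
  if (!is.null(x$ci)) return(x$ci)
  tibble(index = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues)
}

#' @rdname tidy.mc_fim_report
#' @export
glance.mc_fim_report <- function(x, ...) {
  tibble(n_parameters = ncol(x$fim), condition_number = x$condition_number,
         min_eigenvalue = min(x$eigenvalues),
         max_eigenvalue = max(x$eigenvalues),
         singular = x$singular_flag,
         confidence = x$confidence %||% NA_real_,
         n_non_identifiable = length(x$non_identifiable %||% character(0)))
}

#' Tidy a structural-identifiability screen
#'
#' @param x An `mc_sia_report`.
#' @param ... Unused.
#' @return The per-probe rank table.
#' @export
tidy.mc_sia_report <- function(x, ...) x$probes

#' @rdname tidy.mc_sia_report
#' @export
glance.mc_sia_report <- function(x, ...) {
  tibble(scheme = x$scheme, rank = x$rank, n_free = x$n_free,
         deficiency = x$deficiency, verdict = x$verdict)
}

#' Tidy a cross-validation report
#'
#' @param x An `mc_validation_report`.
#' @param ... Unused.
#' @return The per-fold tibble.
#' @export
tidy.mc_validation_report <- function(x, ...) x$folds

#' @rdname tidy.mc_validation_report
#' @export
glance.mc_validation_report <- function(x, ...) {
  tibble(n_folds = nrow(x$folds),
         mean_rmse = x$aggregate$mean_rmse,
         mean_nrmse = x$aggregate$mean_nrmse)
}
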