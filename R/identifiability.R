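#' Compute output sensitivities with respect to the free parameters
#'
#' Local parametric sensitivities \eqn{S = \partial y / \partial \theta}
#' evaluated at every dataset record, either by integrating the forward
#' sensitivity system (`"forward_ode"`: the state equations augmented with
#' \eqn{dS_x/dt = J_x S_x + \partial f/\partial\theta}, using the analytic
#' gLV derivatives when available) or by central finite differences of the
#' simulated observables (`"finite_difference"`). Estimated initial
#' conditions are included with \eqn{S_x(t_0)} equal to the corresponding
#' unit vectors.
#'
#' @param problem An [estimation_problem()].
#' @param theta_eval Free-parameter vector at which to evaluate (typically
#'   the estimate, or the nominal vector in synthetic studies).
#' @param method `"forward_ode"` or `"finite_difference"`.
#' @return An `mc_sensitivity`: `records` (tibble `experiment`,
#'   `observable`, `time`, `sigma`), the `S` matrix (records by free
#'   parameters), `theta_eval` and `method`.
#' @export
compute_sensitivities <- function(problem, theta_eval,
                                  method = c("forward_ode", "finite_difference")) {
  method <- match.arg(method)
  stopifnot(inherits(problem, "mc_problem"))
  phi <- stats::setNames(as.numeric(theta_eval), problem$free_names)
  w <- wls_cost(problem, phi)
  if (w$status != "ok") {
    abort(sprintf("simulation fails (%s) at the evaluation point; run stability/fit checks first",
                  w$status))
  }
  rec_list <- list(); S_list <- list()
  for (e in problem$experiments) {
    d <- problem$designs[[e]]
    x0 <- problem_x0(problem, e, phi)
    S_e <- if (method == "forward_ode") {
      forward_sensitivities(problem, e, phi, x0)
    } else {
      fd_sensitivities(problem, e, phi)
    }
    sub <- problem$dataset[problem$dataset$experiment == e, , drop = FALSE]
    rec_list[[e]] <- tibble(experiment = e, observable = sub$observable,
                            time = sub$time, sigma = sub$sigma)
    S_list[[e]] <- S_e
  }
  S <- do.call(rbind, S_list)
  colnames(S) <- problem$free_names
  structure(list(records = dplyr::bind_rows(rec_list), S = S,
                 theta_eval = phi, method = method),
            class = "mc_sensitivity")
}

# forward sensitivity ODE for one experiment; returns records x n_free
forward_sensitivities <- function(problem, e, phi, x0) {
  model <- problem$model
  d <- problem$designs[[e]]
  N <- model$n_x
  theta <- phi[seq_len(model$n_theta)]
  n_free <- problem$n_free
  # initial sensitivity: identity columns for this experiment's estimated x0
  S0 <- matrix(0, N, n_free)
  for (nm in names(problem$x0_slots)) {
    slot <- problem$x0_slots[[nm]]
    if (slot$experiment == e) S0[slot$state, match(nm, problem$free_names)] <- 1
  }
  dfdtheta <- make_dfdtheta(model)
  aug_rhs <- function(t, y, p) {
    x <- y[seq_len(N)]
    S <- matrix(y[-seq_len(N)], N, n_free)
    Jx <- model_jacobian_x(model, x, theta, t = t)
    dS <- Jx %*% S
    dS[, seq_len(model$n_theta)] <- dS[, seq_len(model$n_theta)] +
      dfdtheta(x, theta)
    list(c(evaluate_rhs(model, x, theta, t = t), as.vector(dS)))
  }
  times <- sort(unique(c(d$t_span[1], unlist(d$sampling_times))))
  out <- deSolve::lsoda(y = c(x0, as.vector(S0)), times = times,
                        func = aug_rhs, parms = NULL,
                        rtol = problem$rtol, atol = problem$atol)
  sens_rows_from_solution(out, d, N, n_free)
}

# analytic df/dtheta for gLV; finite differences otherwise
make_dfdtheta <- function(model) {
  if (model$kind == "glv") {
    N <- model$n_x
    function(x, theta) {
      D <- matrix(0, N, model$n_theta)
      D[cbind(seq_len(N), seq_len(N))] <- x             # d f_i / d mu_i
      for (i in seq_len(N)) {                            # d f_i / d beta_ij
        D[i, N + (i - 1) * N + seq_len(N)] <- x[i] * x
      }
      D
    }
  } else {
    function(x, theta) {
      n_th <- model$n_theta
      D <- matrix(0, model$n_x, n_th)
      for (k in seq_len(n_th)) {
        h <- 1e-6 * max(1, abs(theta[k]))
        tp <- theta; tp[k] <- tp[k] + h
        tm <- theta; tm[k] <- tm[k] - h
        D[, k] <- (model$rhs(x, tp, NULL, 0) - model$rhs(x, tm, NULL, 0)) / (2 * h)
      }
      D
    }
  }
}

# map augmented ODE output (states + state sensitivities) to observable
# sensitivities at the experiment's record times, applying the observation
# chain rule
sens_rows_from_solution <- function(out, d, N, n_free) {
  tt <- out[, 1]
  om <- d$obs_map
  rows <- list()
  for (obs_name in names(d$sampling_times)) {
    o_idx <- match(obs_name, om$obs_names)
    for (ts in d$sampling_times[[obs_name]]) {
      r <- which.min(abs(tt - ts))
      x <- out[r, 1 + seq_len(N)]
      Sx <- matrix(out[r, -(seq_len(N + 1))], N, n_free)
      dg <- obs_gradient(om, x, ts, o_idx)
      rows[[length(rows) + 1L]] <- drop(dg %*% Sx)
    }
  }
  do.call(rbind, rows)
}

obs_gradient <- function(om, x, t, o_idx) {
  if (!is.null(om$C)) return(om$C[o_idx, , drop = FALSE])
  g0 <- om$g(x, t)
  grad <- numeric(length(x))
  for (j in seq_along(x)) {
    h <- 1e-6 * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    grad[j] <- (om$g(xp, t)[o_idx] - om$g(xm, t)[o_idx]) / (2 * h)
  }
  matrix(grad, 1)
}

fd_sensitivities <- function(problem, e, phi) {
  d <- problem$designs[[e]]
  n_free <- problem$n_free
  predict_at <- function(p) {
    pr <- predict_observables(problem$model, p[seq_len(problem$model$n_theta)],
                              d, rtol = problem$rtol, atol = problem$atol,
                              guard_threshold = problem$guard_threshold,
                              x0 = problem_x0(problem, e, p))
    if (pr$status != "ok") abort("finite-difference probe hit a blow-up")
    pr$predictions$value
  }
  cols <- purrr::map(seq_len(n_free), function(k) {
    h <- 1e-5 * max(1, abs(phi[k]))
    pp <- phi; pp[k] <- pp[k] + h
    pm <- phi; pm[k] <- pm[k] - h
    (predict_at(pp) - predict_at(pm)) / (2 * h)
  })
  do.call(cbind, cols)
}

#' Assemble the Fisher information matrix from sensitivities
#'
#' For Gaussian measurement errors with known standard deviations the FIM
#' of the weighted least-squares problem is
#' \eqn{F = \sum_{records} s\, s^\top / \sigma^2} with \eqn{s} the record's
#' sensitivity row. Reports the eigenstructure: small eigenvalues or a
#' large condition number signal practical non-identifiability.
#'
#' @param sens An `mc_sensitivity` from [compute_sensitivities()].
#' @param sigma Optional per-record standard deviations (defaults to the
#'   dataset values carried in `sens$records`).
#' @param singular_tol A singularity is flagged when the smallest
#'   eigenvalue is below `singular_tol` times the largest.
#' @return An `mc_fim_report` with `fim`, `eigenvalues` (sorted
#'   decreasing), `condition_number`, `singular_flag` and the evaluation
#'   point; [cramer_rao_intervals()] fills in covariance, confidence
#'   intervals and the correlation matrix.
#' @export
compute_fim <- function(sens, sigma = NULL, singular_tol = 1e-10) {
  stopifnot(inherits(sens, "mc_sensitivity"))
  S <- sens$S
  if (nrow(S) == 0) abort("no sensitivity records")
  sigma <- sigma %||% sens$records$sigma
  stopifnot(length(sigma) == nrow(S), all(sigma > 0))
  W <- S / sigma
  F_mat <- crossprod(W)
  F_mat <- (F_mat + t(F_mat)) / 2
  ev <- eigen(F_mat, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) > 0) max(ev) / min(ev) else Inf
  structure(
    list(fim = F_mat, eval_point = sens$theta_eval,
         eigenvalues = sort(ev, decreasing = TRUE),
         condition_number = cond,
         singular_flag = min(ev) < singular_tol * max(ev),
         n_records = nrow(S), covariance = NULL, ci = NULL,
         correlation = NULL, confidence = NULL),
    class = "mc_fim_report"
  )
}

#' Cramer-Rao confidence intervals and parameter correlations
#'
#' Inverts the FIM (Moore-Penrose pseudo-inverse with a singularity flag
#' when rank-deficient) to obtain the Cramer-Rao lower bound on the
#' estimator covariance; per-parameter confidence half-widths are
#' `q * sqrt(C_kk)` with `q` the Gaussian (default) or Student-t quantile.
#' Parameters with relative half-width above `wide_threshold` or pairwise
#' correlation above `corr_threshold` in magnitude are listed as
#' practically non-identifiable (reporting conventions, both
#' configurable).
#'
#' @param report An `mc_fim_report` from [compute_fim()].
#' @param theta_hat Parameter estimates (named or in free-parameter order).
#' @param confidence Confidence level (default 0.95).
#' @param use_t Use a Student-t quantile with `n_records - n_theta`
#'   degrees of freedom instead of the Gaussian quantile.
#' @param wide_threshold Relative half-width flag threshold (default 1,
#'   i.e. a 100% relative confidence interval).
#' @param corr_threshold Pairwise-correlation flag threshold (default 0.95).
#' @return The report with `covariance`, `ci` (a tibble with `parameter`,
#'   `estimate`, `sd`, `half_width`, `relative_width`, `flag_wide`),
#'   `correlation` and `non_identifiable` filled in.
#' @export
cramer_rao_intervals <- function(report, theta_hat, confidence = 0.95,
                                 use_t = FALSE, wide_threshold = 1,
                                 corr_threshold = 0.95) {
  stopifnot(inherits(report, "mc_fim_report"))
  F_mat <- report$fim
  p <- ncol(F_mat)
  theta_hat <- as.numeric(theta_hat)
  stopifnot(length(theta_hat) == p)
  C <- if (report$singular_flag) MASS::ginv(F_mat) else {
    tryCatch(solve(F_mat), error = function(e) MASS::ginv(F_mat))
  }
  C <- (C + t(C)) / 2
  vars <- pmax(diag(C), 0)
  q <- if (use_t) {
    stats::qt(1 - (1 - confidence) / 2, df = max(1, report$n_records - p))
  } else stats::qnorm(1 - (1 - confidence) / 2)
  hw <- q * sqrt(vars)
  rel <- hw / pmax(abs(theta_hat), .Machine$double.eps)
  sdv <- sqrt(pmax(vars, 0))
  R <- C / outer(sdv, sdv)
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R <- pmin(pmax(R, -1), 1)
  pn <- names(report$eval_point) %||% paste0("theta_", seq_len(p))
  dimnames(R) <- list(pn, pn)
  ci <- tibble(parameter = pn, estimate = theta_hat, sd = sdv,
               half_width = hw, relative_width = rel,
               flag_wide = rel > wide_threshold)
  high_corr <- which(abs(R) > corr_threshold & upper.tri(R), arr.ind = TRUE)
  non_ident <- union(pn[ci$flag_wide],
                     unique(c(pn[high_corr[, 1]], pn[high_corr[, 2]])))
  report$covariance <- C
  report$ci <- ci
  report$correlation <- R
  report$confidence <- confidence
  report$non_identifiable <- non_ident
  report
}

#' @export
print.mc_fim_report <- function(x, ...) {
  cat(sprintf("<mc_fim_report> %d parameter(s), condition number %.3g%s\n",
              ncol(x$fim), x$condition_number,
              if (x$singular_flag) " [singular]" else ""))
  invisible(x)
}

#' Local structural-identifiability rank screen
#'
#' A numeric surrogate for pre-estimation structural-identifiability
#' analysis: noise-free output sensitivities on a dense sampling grid are
#' stacked into an identifiability matrix whose singular-value rank decides
#' the verdict. Rank deficiency exposes parameter directions (the numeric
#' null space) that cannot be locally distinguished from the chosen
#' observation scheme. The test is repeated at several random parameter
#' probes and decided by majority, to avoid atypical points; probes whose
#' simulation blows up are resampled (bounded retries). The verdict is a
#' statement about *local* identifiability only — a necessary condition for
#' global identifiability, never a proof of it.
#'
#' @param model An [mc_model][glv_model()].
#' @param obs_map An [observation_map()] defining the scheme under test.
#' @param design Optional [experiment_design()]; defaults to a dense
#'   noise-free design on `[0, 10]` with `max(30, 3 * n_free)` sampling
#'   points started from `x0`.
#' @param x0 Initial state for the default design (default: 0.1 for every
#'   species).
#' @param estimate_x0 Treat the initial conditions as unknown free
#'   quantities of the scheme (the realistic partially-observed setting).
#' @param theta_probe Optional explicit probe; otherwise probes are drawn
#'   from the model bounds (or around `model$nominal_theta` when set).
#' @param n_probes Number of probes for the majority verdict (default 3).
#' @param seed Seed for probe sampling.
#' @param rank_tol Singular values below `rank_tol * largest` count as
#'   zero (default 1e-8).
#' @return An `mc_sia_report`: `scheme`, `rank`, `n_free`, `deficiency`,
#'   `verdict` (`"locally_identifiable"` iff deficiency is zero by
#'   majority), `implicated` (null-space directions, columns named by the
#'   free parameters) and the per-probe table.
#' @export
local_sia_rank <- function(model, obs_map, design = NULL, x0 = NULL,
                           estimate_x0 = FALSE, theta_probe = NULL,
                           n_probes = 3, seed = 1, rank_tol = 1e-8) {
  stopifnot(inherits(model, "mc_model"), inherits(obs_map, "mc_obs_map"))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  x0 <- x0 %||% rep(0.1, model$n_x)
  if (is.null(design)) {
    n_free_guess <- model$n_theta + if (estimate_x0) model$n_x else 0
    n_pts <- max(30, 3 * n_free_guess)
    design <- experiment_design(
      "sia_probe", x0 = x0, t_span = c(0, 10),
      sampling_times = seq(0.1, 10, length.out = n_pts),
      obs_map = obs_map,
      estimate_x0 = rep(estimate_x0, model$n_x),
      x0_bounds = if (estimate_x0)
        matrix(rep(c(1e-4, 10), each = model$n_x), model$n_x, 2) else NULL
    )
  }

  draw_probe <- function() {
    if (!is.null(model$nominal_theta)) {
      model$nominal_theta * (1 + stats::runif(model$n_theta, -0.2, 0.2))
    } else {
      model$bounds[, 1] + stats::runif(model$n_theta) *
        (model$bounds[, 2] - model$bounds[, 1])
    }
  }

  probe_results <- list()
  attempts <- 0
  while (length(probe_results) < n_probes && attempts < 25 * n_probes) {
    attempts <- attempts + 1
    th <- if (!is.null(theta_probe) && length(probe_results) == 0) {
      as.numeric(theta_probe)
    } else draw_probe()
    tr <- simulate_model(model, th, design = design)
    if (trajectory_status(tr) != "ok") next
    dataset <- noise_free_records(model, th, design)
    prob <- estimation_problem(model, list(design), dataset)
    sens <- tryCatch(compute_sensitivities(prob, c(th, design$x0[design$estimate_x0]),
                                           method = "forward_ode"),
                     error = function(e) NULL)
    if (is.null(sens)) next
    sv <- svd(sens$S)
    rnk <- sum(sv$d > rank_tol * max(sv$d))
    null_dirs <- if (rnk < ncol(sens$S)) {
      V <- sv$v[, (rnk + 1):ncol(sens$S), drop = FALSE]
      rownames(V) <- prob$free_names
      V
    } else NULL
    probe_results[[length(probe_results) + 1L]] <-
      list(theta = th, rank = rnk, n_free = ncol(sens$S),
           null_dirs = null_dirs, singular_values = sv$d)
  }
  if (length(probe_results) == 0) {
    abort("no probe simulated cleanly; widen bounds or supply theta_probe")
  }
  ranks <- purrr::map_int(probe_results, "rank")
  n_free <- probe_results[[1]]$n_free
  rank_major <- as.integer(stats::median(ranks))
  deficiency <- n_free - rank_major
  # implicated directions from a probe realizing the majority rank
  pick <- which(ranks == rank_major)[1]
  structure(
    list(scheme = obs_map$scheme, rank = rank_major, n_free = n_free,
         deficiency = deficiency,
         verdict = if (deficiency == 0) "locally_identifiable"
                   else "locally_non_identifiable",
         implicated = probe_results[[pick]]$null_dirs,
         probes = tibble(probe = seq_along(ranks), rank = ranks,
                         n_free = n_free),
         rank_tol = rank_tol),
    class = "mc_sia_report"
  )
}

noise_free_records <- function(model, theta, design) {
  pr <- predict_observables(model, theta, design)
  stopifnot(pr$status == "ok")
  p <- pr$predictions
  new_dataset(tibble(experiment = design$experiment_id,
                     observable = p$observable, time = p$time,
                     value = p$value, sigma = 1))
}

#' @export
print.mc_sia_report <- function(x, ...) {
  cat(sprintf("<mc_sia_report> scheme=%s rank=%d/%d -> %s\n",
              x$scheme, x$rank, x$n_free, x$verdict))
  invisible(x)
}

#' Sign agreement between estimated and nominal parameters
#'
#' The fraction of (masked) parameters whose estimated sign matches the
#' nominal sign — the mechanistic-interpretation check for interaction
#' coefficients, where a flipped sign turns e.g. facilitation into
#' competition. Nominal values within `dead_band` of zero are compared as
#' zeros.
#'
#' @param theta_hat,theta_nominal Equal-length parameter vectors.
#' @param subset Optional logical mask or index vector selecting the
#'   entries to compare (e.g. only interaction coefficients).
#' @param dead_band Magnitudes below this count as zero sign.
#' @return A list with `agreement` (fraction in `[0, 1]`) and a
#'   per-parameter tibble.
#' @export
sign_agreement <- function(theta_hat, theta_nominal, subset = NULL,
                           dead_band = 1e-8) {
  if (length(theta_hat) != length(theta_nominal)) {
    abort("estimate and nominal vectors must have the same length")
  }
  nm <- names(theta_hat) %||% paste0("theta_", seq_along(theta_hat))
  idx <- if (is.null(subset)) seq_along(theta_hat)
         else if (is.logical(subset)) which(subset) else as.integer(subset)
  soft_sign <- function(v) ifelse(abs(v) <= dead_band, 0, sign(v))
  tab <- tibble(
    parameter = nm[idx],
    estimate = as.numeric(theta_hat[idx]),
    nominal = as.numeric(theta_nominal[idx]),
    agree = soft_sign(as.numeric(theta_hat[idx])) ==
            soft_sign(as.numeric(theta_nominal[idx]))
  )
  list(agreement = mean(tab$agree), table = tab)
}
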