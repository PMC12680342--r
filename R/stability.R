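#' Find equilibria of a community model
#'
#' For gLV models all `2^N` support patterns are enumerated: for each
#' candidate set of surviving species the linear system
#' `beta[s, s] x_s = -mu_s` is solved and solutions with strictly positive
#' support entries (and zeros elsewhere) are kept — including the
#' extinction equilibrium at the origin. Supports with a singular
#' interaction submatrix are skipped and recorded as degenerate. General
#' models use damped-Newton multistart root finding from a space-filling
#' sample of the search box, deduplicated by distance. Each equilibrium is
#' classified by [classify_equilibrium()].
#'
#' @param model An [mc_model][glv_model()].
#' @param theta Parameter vector.
#' @param nonnegative_only Keep only non-negative equilibria (abundances);
#'   set `FALSE` to expose the full set for diagnostics.
#' @param search_box `n_x x 2` matrix of state bounds (required for
#'   general models).
#' @param n_starts Multistart count for general models.
#' @param seed Seed for the multistart sample.
#' @param tol Residual tolerance `|f(x*)| <= tol * (1 + |x*|)`.
#' @return An `mc_equilibria` tibble: one row per equilibrium with the
#'   state coordinates, `support`, `class`, `max_re`, `residual_norm`,
#'   and an `eigenvalues` list-column. Degenerate supports are listed in
#'   the `degenerate_supports` attribute.
#' @examples
#' logistic <- glv_model(1, matrix(-1, 1, 1))
#' find_equilibria(logistic, c(1, -1))
#' @export
find_equilibria <- function(model, theta, nonnegative_only = TRUE,
                            search_box = NULL, n_starts = 50, seed = 1,
                            tol = 1e-9) {
  stopifnot(inherits(model, "mc_model"))
  if (model$kind == "glv") {
    N <- model$n_x
    if (N > 15) abort("support enumeration is limited to 15 species")
    p <- glv_unpack(theta, N)
    points <- list(rep(0, N))
    degenerate <- character(0)
    for (mask in seq_len(2^N - 1)) {
      s <- which(bitwAnd(mask, 2^(seq_len(N) - 1)) > 0)
      B <- p$beta[s, s, drop = FALSE]
      xs <- tryCatch(solve(B, -p$mu[s]), error = function(e) NULL)
      if (is.null(xs) || any(!is.finite(xs))) {
        degenerate <- c(degenerate, paste(s, collapse = ","))
        next
      }
      if (any(abs(xs) < 1e-12)) next  # collapses onto a smaller support
      if (nonnegative_only && any(xs < 0)) next
      x_star <- rep(0, N); x_star[s] <- xs
      points[[length(points) + 1L]] <- x_star
    }
  } else {
    if (is.null(search_box)) abort("general models need a search_box")
    points <- newton_multistart(model, theta, search_box, n_starts, seed, tol)
    degenerate <- character(0)
  }
  points <- dedupe_points(points)
  rows <- purrr::map(points, function(x_star) {
    classify_equilibrium(model, theta, x_star, tol = tol)
  })
  tb <- dplyr::bind_rows(rows)
  structure(tb, degenerate_supports = degenerate,
            class = c("mc_equilibria", class(tb)))
}

newton_multistart <- function(model, theta, search_box, n_starts, seed, tol) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  lo <- search_box[, 1]; up <- search_box[, 2]
  starts <- sweep(sweep(lhs::randomLHS(n_starts, model$n_x), 2, up - lo, `*`),
                  2, lo, `+`)
  sols <- list()
  for (k in seq_len(n_starts)) {
    x <- starts[k, ]
    for (it in 1:60) {
      fx <- model$rhs(x, theta, NULL, 0)
      if (!all(is.finite(fx))) break
      if (sqrt(sum(fx^2)) <= tol * (1 + sqrt(sum(x^2)))) {
        sols[[length(sols) + 1L]] <- x
        break
      }
      J <- model_jacobian_x(model, x, theta)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        xn <- x + lambda * step
        fn <- model$rhs(xn, theta, NULL, 0)
        if (all(is.finite(fn)) && sum(fn^2) < sum(fx^2)) break
        lambda <- lambda / 2
        if (lambda < 1e-6) { xn <- x + 1e-6 * step; break }
      }
      x <- xn
    }
  }
  sols
}

dedupe_points <- function(points, dist_tol = 1e-6) {
  keep <- list()
  for (x in points) {
    dup <- any(purrr::map_lgl(keep, function(y) {
      sqrt(sum((x - y)^2)) < dist_tol * (1 + sqrt(sum(y^2)))
    }))
    if (!dup) keep[[length(keep) + 1L]] <- x
  }
  keep
}

#' Classify an equilibrium from Jacobian eigenvalues
#'
#' Linearizes at the candidate equilibrium and applies the eigenvalue
#' rule: all real parts negative is asymptotically stable; at least one
#' positive is unstable (a saddle when signs mix among the nonzero real
#' parts); all non-positive with some within `eps_stab` of zero is
#' neutral (linearization inconclusive, e.g. a center — flagged for
#' simulation-based follow-up). Nodes and spirals are distinguished by
#' the presence of imaginary parts.
#'
#' @param model An [mc_model][glv_model()].
#' @param theta Parameter vector.
#' @param x_star Candidate equilibrium state.
#' @param eps_stab Real parts within this of zero count as zero
#'   (default 1e-8).
#' @param tol Residual tolerance; a point failing
#'   `|f(x*)| <= tol * (1 + |x*|)` is rejected as not an equilibrium.
#' @return A one-row tibble with the state, `support`, `class`,
#'   `max_re`, `residual_norm` and an `eigenvalues` list-column.
#' @export
classify_equilibrium <- function(model, theta, x_star, eps_stab = 1e-8,
                                 tol = 1e-9) {
  x_star <- as.numeric(x_star)
  fx <- evaluate_rhs(model, x_star, theta)
  resid <- sqrt(sum(fx^2))
  if (resid > tol * (1 + sqrt(sum(x_star^2)))) {
    abort(sprintf("point is not an equilibrium (|rhs| = %.3g)", resid))
  }
  J <- model_jacobian_x(model, x_star, theta)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev); im <- Im(ev)
  has_pos <- any(re > eps_stab)
  has_neg <- any(re < -eps_stab)
  has_zero <- any(abs(re) <= eps_stab)
  spiral <- any(abs(im) > eps_stab)
  class <- if (has_pos && has_neg) "saddle"
    else if (has_pos) { if (spiral) "unstable_spiral" else "unstable_node" }
    else if (has_zero) "neutral"
    else if (spiral) "stable_spiral" else "stable_node"
  st <- stats::setNames(as.list(x_star), model$state_names)
  dplyr::bind_cols(
    as_tibble(st),
    tibble(support = paste(which(abs(x_star) > 1e-12), collapse = ","),
           class = class, max_re = max(re), residual_norm = resid,
           eigenvalues = list(ev))
  )
}

#' Screen a calibrated fit for long-term dynamic stability
#'
#' A parameter set can match the data window well yet diverge beyond it —
#' locally valid but globally unstable. The screen extends every
#' experiment's simulation to `horizon_factor` times its data window and,
#' for gLV models, classifies the equilibria and relates each trajectory
#' endpoint to the nearest one. The verdict is `"plausible"` only when no
#' trajectory diverges on the extended horizon.
#'
#' @param fit An `mc_fit` (or a bare parameter vector).
#' @param problem The [estimation_problem()] the fit belongs to.
#' @param horizon_factor Horizon multiplier (> 1), default 3.
#' @return A list with `verdict` (`"plausible"` or
#'   `"locally_valid_but_unstable"`), per-experiment `evidence`, and the
#'   `equilibria` table when available.
#' @export
stability_screen <- function(fit, problem, horizon_factor = 3) {
  theta <- if (inherits(fit, "mc_fit")) fit$theta else fit
  phi <- stats::setNames(as.numeric(theta), problem$free_names)
  model <- problem$model
  ev <- purrr::map(problem$experiments, function(e) {
    d <- problem$designs[[e]]
    chk <- long_horizon_check(model, phi[seq_len(model$n_theta)],
                              x0 = problem_x0(problem, e, phi),
                              t0 = d$t_span[1], tf_data = d$t_span[2],
                              horizon_factor = horizon_factor,
                              rtol = problem$rtol, atol = problem$atol)
    tibble(experiment = e, stable_on_horizon = chk$stable_on_horizon,
           t_divergence = chk$t_divergence, status = chk$status)
  })
  evidence <- dplyr::bind_rows(ev)
  eq <- if (model$kind == "glv" && model$n_x <= 15) {
    tryCatch(find_equilibria(model, phi[seq_len(model$n_theta)]),
             error = function(e) NULL)
  } else NULL
  verdict <- if (all(evidence$stable_on_horizon)) "plausible"
             else "locally_valid_but_unstable"
  list(verdict = verdict, evidence = evidence, equilibria = eq,
       horizon_factor = horizon_factor)
}
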