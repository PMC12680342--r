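#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_lgl imap
NULL

#' Construct a dense generalized Lotka-Volterra model
#'
#' Builds the community model
#' \deqn{\frac{dx_i}{dt} = x_i \Big(\mu_i + \sum_{j=1}^{N} \beta_{ij} x_j\Big)}
#' with per-species growth rates \eqn{\mu_i} and a full pairwise interaction
#' matrix \eqn{\beta}. The parameter vector has length \eqn{N + N^2} and is
#' laid out as `c(mu_1, ..., mu_N, beta_11, beta_12, ..., beta_NN)` (the
#' interaction matrix in row-major order); this layout is fixed and used by
#' all estimation, identifiability and I/O code.
#'
#' @param growth_rates Numeric vector of length `N`, nominal growth rates.
#' @param interaction_matrix Numeric `N x N` matrix of nominal interaction
#'   coefficients (`beta[i, j]` is the effect of species `j` on species `i`).
#' @param bounds Parameter-space bounds used by estimation. Either a list
#'   with elements `mu = c(lo, hi)` and `beta = c(lo, hi)` applied blockwise,
#'   or an `n_theta x 2` matrix. Defaults to growth rates in `[-5, 5]` and
#'   interactions in `[-5, 5]`.
#' @param state_names Optional species labels; defaults to `x1 ... xN`.
#'
#' @return An object of class `mc_model` with `kind = "glv"`, carrying the
#'   right-hand side, its analytic state Jacobian, parameter names and
#'   bounds. The nominal values passed here are *not* stored as truth; they
#'   only initialise `nominal_theta` for convenience in synthetic studies.
#'
#' @examples
#' m <- glv_model(c(1, 0.8), matrix(c(-1, -0.4, -0.3, -0.8), 2, byrow = TRUE))
#' m$n_theta # 6
#' @export
glv_model <- function(growth_rates, interaction_matrix,
                      bounds = list(mu = c(-5, 5), beta = c(-5, 5)),
                      state_names = NULL) {
  growth_rates <- as.numeric(growth_rates)
  N <- length(growth_rates)
  if (N < 1) abort("need at least one species")
  interaction_matrix <- as.matrix(interaction_matrix)
  if (nrow(interaction_matrix) != N || ncol(interaction_matrix) != N) {
    abort(sprintf("interaction matrix must be %d x %d, got %d x %d",
                  N, N, nrow(interaction_matrix), ncol(interaction_matrix)))
  }
  if (!all(is.finite(growth_rates)) || !all(is.finite(interaction_matrix))) {
    abort("growth rates and interaction coefficients must be finite")
  }
  state_names <- state_names %||% paste0("x", seq_len(N))
  stopifnot(length(state_names) == N, !anyDuplicated(state_names))

  n_theta <- N + N * N
  param_names <- c(
    paste0("mu_", seq_len(N)),
    paste0("beta_", rep(seq_len(N), each = N), "_", rep(seq_len(N), N))
  )
  bounds <- resolve_glv_bounds(bounds, N, n_theta, param_names)

  rhs <- function(x, theta, u = NULL, t = 0) {
    p <- glv_unpack(theta, N)
    x * (p$mu + drop(p$beta %*% x))
  }
  jac_x <- function(x, theta, u = NULL, t = 0) {
    p <- glv_unpack(theta, N)
    diag(drop(p$mu + p$beta %*% x), N) + x * p$beta
  }

  structure(
    list(
      kind = "glv", n_x = N, state_names = state_names,
      n_theta = n_theta, param_names = param_names, bounds = bounds,
      rhs = rhs, jacobian_x = jac_x, input_profile = NULL,
      nominal_theta = glv_pack(growth_rates, interaction_matrix)
    ),
    class = "mc_model"
  )
}

resolve_glv_bounds <- function(bounds, N, n_theta, param_names) {
  if (is.matrix(bounds)) {
    b <- bounds
  } else {
    stopifnot(is.list(bounds), length(bounds$mu) == 2, length(bounds$beta) == 2)
    b <- rbind(
      matrix(rep(bounds$mu, each = N), N, 2),
      matrix(rep(bounds$beta, each = N * N), N * N, 2)
    )
  }
  check_bounds(b, n_theta, param_names)
}

check_bounds <- function(b, n_theta, param_names) {
  b <- as.matrix(b)
  if (nrow(b) != n_theta || ncol(b) != 2) {
    abort(sprintf("bounds must be %d x 2", n_theta))
  }
  if (!all(is.finite(b))) abort("bounds must be finite")
  if (any(b[, 1] >= b[, 2])) abort("each lower bound must be below its upper bound")
  dimnames(b) <- list(param_names, c("lower", "upper"))
  b
}

#' Construct a general ODE model
#'
#' Wraps a user-supplied deterministic right-hand side `rhs(x, theta, u, t)`
#' into the same interface as [glv_model()], so that simulation, estimation
#' and identifiability analysis apply unchanged. State Jacobians default to
#' central finite differences when not supplied.
#'
#' @param rhs Function `(x, theta, u, t) -> dx/dt` returning a vector of
#'   length `n_x`.
#' @param n_x Number of state variables.
#' @param param_names Unique parameter labels.
#' @param bounds `n_theta x 2` matrix (or list of length-2 vectors, one per
#'   parameter) of finite lower/upper bounds.
#' @param state_names Optional state labels.
#' @param jacobian_x Optional analytic state Jacobian `(x, theta, u, t)`.
#' @param input_profile Optional input function `t -> u` for forced systems.
#' @param nominal_theta Optional nominal parameter vector (synthetic studies).
#'
#' @return An `mc_model` with `kind = "general"`.
#' @export
general_model <- function(rhs, n_x, param_names, bounds,
                          state_names = NULL, jacobian_x = NULL,
                          input_profile = NULL, nominal_theta = NULL) {
  stopifnot(is.function(rhs), n_x >= 1)
  param_names <- as.character(param_names)
  if (anyDuplicated(param_names)) abort("parameter names must be unique")
  n_theta <- length(param_names)
  if (is.list(bounds) && !is.matrix(bounds)) bounds <- do.call(rbind, bounds)
  bounds <- check_bounds(bounds, n_theta, param_names)
  state_names <- state_names %||% paste0("x", seq_len(n_x))
  stopifnot(length(state_names) == n_x)
  structure(
    list(
      kind = "general", n_x = as.integer(n_x), state_names = state_names,
      n_theta = n_theta, param_names = param_names, bounds = bounds,
      rhs = rhs, jacobian_x = jacobian_x, input_profile = input_profile,
      nominal_theta = nominal_theta
    ),
    class = "mc_model"
  )
}

#' @export
print.mc_model <- function(x, ...) {
  cat(sprintf("<mc_model> kind=%s, n_x=%d, n_theta=%d\n",
              x$kind, x$n_x, x$n_theta))
  invisible(x)
}

glv_pack <- function(mu, beta) c(mu, as.vector(t(beta)))

glv_unpack <- function(theta, N) {
  list(mu = theta[seq_len(N)],
       beta = matrix(theta[-seq_len(N)], N, N, byrow = TRUE))
}

#' Evaluate a model right-hand side
#'
#' @param model An [mc_model][glv_model()].
#' @param x State vector of length `model$n_x`.
#' @param theta Parameter vector of length `model$n_theta`.
#' @param u Optional input value; defaults to the model's `input_profile`
#'   evaluated at `t` when one exists.
#' @param t Time.
#' @return Derivative vector `dx/dt`.
#' @export
evaluate_rhs <- function(model, x, theta, u = NULL, t = 0) {
  stopifnot(inherits(model, "mc_model"))
  if (length(x) != model$n_x) {
    abort(sprintf("state has length %d, expected %d", length(x), model$n_x))
  }
  if (length(theta) != model$n_theta) {
    abort(sprintf("theta has length %d, expected %d", length(theta), model$n_theta))
  }
  if (!all(is.finite(x)) || !all(is.finite(theta))) {
    abort("state and parameters must be finite")
  }
  if (is.null(u) && !is.null(model$input_profile)) u <- model$input_profile(t)
  dx <- model$rhs(x, theta, u, t)
  if (length(dx) != model$n_x) abort("rhs returned wrong dimension")
  dx
}

model_jacobian_x <- function(model, x, theta, u = NULL, t = 0, h = 1e-6) {
  if (!is.null(model$jacobian_x)) return(model$jacobian_x(x, theta, u, t))
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    step <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + step
    xm <- x; xm[j] <- xm[j] - step
    J[, j] <- (model$rhs(xp, theta, u, t) - model$rhs(xm, theta, u, t)) / (2 * step)
  }
  J
}

#' Construct an observation map
#'
#' Observation maps connect model states to measured quantities. Supported
#' schemes: `"fo"` (fully observed, identity), `"po_subset"` (a subset of
#' individual species), `"po_sum"` (a single aggregate observable, e.g.
#' total biomass over the listed species) and `"custom"` (user function).
#'
#' @param scheme One of `"fo"`, `"po_subset"`, `"po_sum"`, `"custom"`.
#' @param n_x Number of state variables being observed.
#' @param indices State indices for the `po_*` schemes.
#' @param g Observation function `(x, t) -> y` for `scheme = "custom"`.
#' @param n_o Number of observables for `scheme = "custom"`.
#'
#' @return An `mc_obs_map` with fields `n_o`, `g`, `scheme`, and, for the
#'   linear schemes, the observation matrix `C` such that `y = C x`.
#' @examples
#' om <- observation_map("po_sum", n_x = 2, indices = 1:2)
#' om$g(c(0.3, 0.7)) # total biomass 1.0
#' @export
observation_map <- function(scheme = c("fo", "po_subset", "po_sum", "custom"),
                            n_x, indices = NULL, g = NULL, n_o = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n_x >= 1)
  if (scheme %in% c("po_subset", "po_sum")) {
    if (length(indices) == 0) abort("partial-observation schemes need a non-empty index list")
    indices <- as.integer(indices)
    if (any(indices < 1 | indices > n_x)) {
      abort(sprintf("observation indices out of range 1..%d", n_x))
    }
  }
  C <- switch(scheme,
    fo = diag(1, n_x),
    po_subset = diag(1, n_x)[indices, , drop = FALSE],
    po_sum = matrix(as.numeric(seq_len(n_x) %in% indices), 1, n_x),
    custom = NULL
  )
  if (scheme == "custom") {
    stopifnot(is.function(g), !is.null(n_o))
    gg <- g
    no <- as.integer(n_o)
    obs_names <- paste0("y", seq_len(no))
  } else {
    no <- nrow(C)
    gg <- function(x, t = 0) drop(C %*% x)
    obs_names <- switch(scheme,
      fo = paste0("y", seq_len(n_x)),
      po_subset = paste0("y", indices),
      po_sum = "y_total"
    )
  }
  structure(
    list(n_o = no, n_x = as.integer(n_x), g = gg, C = C, scheme = scheme,
         indices = indices, obs_names = obs_names),
    class = "mc_obs_map"
  )
}

#' Define an experiment design
#'
#' An experiment couples initial conditions, a time span, per-observable
#' sampling times and an observation map. Initial-condition entries may be
#' marked for estimation; they are then appended to the free parameter
#' vector by [estimation_problem()].
#'
#' @param experiment_id Label, unique within a study.
#' @param x0 Initial state vector.
#' @param t_span `c(t0, tf)` with `t0 < tf`.
#' @param sampling_times Numeric vector of sampling times (shared by all
#'   observables) or a named list with one sorted vector per observable
#'   name of the observation map.
#' @param obs_map An [observation_map()].
#' @param estimate_x0 Logical mask (length `n_x`): which initial conditions
#'   are unknown and to be estimated.
#' @param x0_bounds `n_x x 2` matrix of bounds for estimated entries.
#' @return An `mc_design`.
#' @export
experiment_design <- function(experiment_id, x0, t_span, sampling_times,
                              obs_map, estimate_x0 = NULL, x0_bounds = NULL) {
  stopifnot(inherits(obs_map, "mc_obs_map"))
  x0 <- as.numeric(x0)
  if (length(x0) != obs_map$n_x) {
    abort(sprintf("x0 has length %d but the observation map expects n_x=%d",
                  length(x0), obs_map$n_x))
  }
  t_span <- as.numeric(t_span)
  if (length(t_span) != 2 || !(t_span[1] < t_span[2])) abort("need t0 < tf")
  if (!is.list(sampling_times)) {
    sampling_times <- stats::setNames(
      rep(list(sort(as.numeric(sampling_times))), obs_map$n_o),
      obs_map$obs_names
    )
  }
  for (nm in names(sampling_times)) {
    ts <- sampling_times[[nm]]
    if (is.unsorted(ts)) abort("sampling times must be sorted")
    if (any(ts < t_span[1] | ts > t_span[2])) {
      abort("sampling times must lie inside the experiment time span")
    }
  }
  estimate_x0 <- estimate_x0 %||% rep(FALSE, length(x0))
  stopifnot(length(estimate_x0) == length(x0))
  if (any(estimate_x0) && is.null(x0_bounds)) {
    abort("x0_bounds required when initial conditions are estimated")
  }
  structure(
    list(experiment_id = as.character(experiment_id), x0 = x0,
         t_span = t_span, sampling_times = sampling_times,
         obs_map = obs_map, estimate_x0 = estimate_x0, x0_bounds = x0_bounds),
    class = "mc_design"
  )
}
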