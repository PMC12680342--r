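#' Built-in case-study fixtures
#'
#' Ready-made benchmark communities of increasing complexity, mirroring
#' the canonical model sizes used throughout the package: a two-species
#' gLV (competition and coexistence subcases, 6 parameters), a
#' three-species gLV (12 parameters) and a 12-species gut-microbiome-style
#' gLV (156 parameters). The nominal parameter values are synthetic
#' defaults chosen for ecological plausibility (growth rates of order one,
#' self-limiting species, stable community attractors); they are generator
#' defaults, not transcriptions of any published community. Each fixture
#' ships two experiments with different initial conditions so held-out
#' cross-validation is possible out of the box.
#'
#' @param case For `glv2_fixture()`: `"coexistence"` (weak interspecific
#'   competition, stable interior equilibrium) or `"competition"` (strong
#'   interspecific competition, bistable exclusion).
#' @param t_grid Sampling times shared by every observable (defaults per
#'   fixture).
#' @return A list with `name`, `model` (an [mc_model][glv_model()]),
#'   `theta_nominal`, and `designs` (fully-observed experiment designs).
#' @examples
#' fx <- glv2_fixture()
#' fx$model$n_theta # 6
#' @export
glv2_fixture <- function(case = c("coexistence", "competition"),
                         t_grid = seq(0.5, 10, length.out = 12)) {
  case <- match.arg(case)
  mu <- c(1.0, 0.8)
  beta <- switch(case,
    coexistence = matrix(c(-1.0, -0.4,
                           -0.3, -0.8), 2, 2, byrow = TRUE),
    competition = matrix(c(-1.0, -1.4,
                           -1.2, -0.8), 2, 2, byrow = TRUE)
  )
  model <- glv_model(mu, beta, bounds = list(mu = c(0, 2), beta = c(-3, 3)))
  om <- observation_map("fo", n_x = 2)
  designs <- list(
    experiment_design("exp1", x0 = c(0.2, 0.2), t_span = c(0, 10),
                      sampling_times = t_grid, obs_map = om),
    experiment_design("exp2", x0 = c(0.05, 0.4), t_span = c(0, 10),
                      sampling_times = t_grid, obs_map = om)
  )
  list(name = paste0("glv2_", case), model = model,
       theta_nominal = model$nominal_theta, designs = designs)
}

#' @rdname glv2_fixture
#' @export
glv3_fixture <- function(t_grid = seq(0.5, 5, length.out = 10)) {
  mu <- c(0.8, 1.2, 1.0)
  beta <- matrix(c(-1.0, -0.5, -0.2,
                   -0.4, -1.2, -0.6,
                   -0.3, -0.1, -0.9), 3, 3, byrow = TRUE)
  model <- glv_model(mu, beta, bounds = list(mu = c(0, 2), beta = c(-3, 3)))
  om <- observation_map("fo", n_x = 3)
  designs <- list(
    experiment_design("exp1", x0 = c(0.1, 0.2, 0.15), t_span = c(0, 5),
                      sampling_times = t_grid, obs_map = om),
    experiment_design("exp2", x0 = c(0.4, 0.05, 0.3), t_span = c(0, 5),
                      sampling_times = t_grid, obs_map = om)
  )
  list(name = "glv3", model = model, theta_nominal = model$nominal_theta,
       designs = designs)
}

#' @rdname glv2_fixture
#' @param n_species Community size for the large fixture (default 12).
#' @export
mglv_fixture <- function(n_species = 12,
                         t_grid = seq(0.5, 5, length.out = 8)) {
  N <- as.integer(n_species)
  # fixed-seed synthetic community: self-limiting diagonal, weak sparse
  # off-diagonal interactions of mixed sign, growth rates of order one
  old <- .Random.seed_guard(20260101L)
  on.exit(old(), add = TRUE)
  mu <- stats::runif(N, 0.3, 1.2)
  beta <- matrix(stats::rnorm(N * N, 0, 0.15), N, N)
  beta[stats::runif(N * N) < 0.5] <- 0
  diag(beta) <- -stats::runif(N, 0.8, 1.5)
  model <- glv_model(mu, beta, bounds = list(mu = c(0, 2), beta = c(-3, 3)))
  om <- observation_map("fo", n_x = N)
  x0a <- stats::runif(N, 0.05, 0.3)
  x0b <- stats::runif(N, 0.05, 0.3)
  designs <- list(
    experiment_design("exp1", x0 = x0a, t_span = c(0, 5),
                      sampling_times = t_grid, obs_map = om),
    experiment_design("exp2", x0 = x0b, t_span = c(0, 5),
                      sampling_times = t_grid, obs_map = om)
  )
  list(name = sprintf("mglv%d", N), model = model,
       theta_nominal = model$nominal_theta, designs = designs)
}

#' Look up a fixture by name
#'
#' @param name One of `"glv2_coexistence"`, `"glv2_competition"`,
#'   `"glv3"`, `"mglv12"`.
#' @return The fixture list (see [glv2_fixture()]).
#' @export
get_fixture <- function(name) {
  switch(name,
    glv2_coexistence = glv2_fixture("coexistence"),
    glv2_competition = glv2_fixture("competition"),
    glv3 = glv3_fixture(),
    mglv12 = mglv_fixture(12),
    abort(sprintf("unknown fixture '%s'", name))
  )
}
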