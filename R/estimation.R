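#' Define a parameter-estimation problem
#'
#' Couples a model, its experiment designs and a measured dataset into the
#' weighted least-squares estimation problem
#' \deqn{J(\theta) = \sum_e \sum_o \sum_s
#'   \Big[\frac{ym_s^{e,o} - y_s^{e,o}(\theta, t_s^{e,o})}{\sigma_s^{e,o}}\Big]^2}
#' subject to the ODE dynamics and box bounds on the parameters. Initial
#' conditions marked `estimate_x0` in a design are appended to the free
#' parameter vector (named `x0_<experiment>_<state>`).
#'
#' @param model An [mc_model][glv_model()].
#' @param designs List of [experiment_design()]s covering every experiment
#'   id present in the dataset.
#' @param dataset An `mc_dataset` (see [generate_dataset()] /
#'   [read_dataset()]).
#' @param rtol,atol,guard_threshold Passed to the simulator for every
#'   objective evaluation.
#' @return An `mc_problem` with the free-parameter layout, bounds and
#'   record bookkeeping used by [wls_cost()], [multistart_local()] and
#'   [ess_optimize()].
#' @export
estimation_problem <- function(model, designs, dataset, rtol = 1e-8,
                               atol = 1e-10, guard_threshold = NULL) {
  if (inherits(designs, "mc_design")) designs <- list(designs)
  stopifnot(inherits(model, "mc_model"))
  design_ids <- purrr::map_chr(designs, "experiment_id")
  names(designs) <- design_ids
  dataset <- new_dataset(as_tibble(dataset), attr(dataset, "provenance"))
  ids <- unique(dataset$experiment)
  missing_ids <- setdiff(ids, design_ids)
  if (length(missing_ids)) {
    abort(sprintf("no design for experiment(s): %s",
                  paste(missing_ids, collapse = ", ")))
  }

  # effective designs: prediction grids taken from the dataset records
  eff <- purrr::map(ids, function(e) {
    d <- designs[[e]]
    sub <- dataset[dataset$experiment == e, , drop = FALSE]
    bad_obs <- setdiff(unique(sub$observable), d$obs_map$obs_names)
    if (length(bad_obs)) {
      abort(sprintf("experiment '%s' has records for unknown observable(s): %s",
                    e, paste(bad_obs, collapse = ", ")))
    }
    st <- split(sub$time, sub$observable)
    d$sampling_times <- st[sort(names(st))]
    d
  })
  names(eff) <- ids

  free_names <- model$param_names
  lower <- model$bounds[, 1]; upper <- model$bounds[, 2]
  x0_slots <- list()
  for (e in ids) {
    d <- eff[[e]]
    if (any(d$estimate_x0)) {
      for (i in which(d$estimate_x0)) {
        nm <- sprintf("x0_%s_%s", e, model$state_names[i])
        free_names <- c(free_names, nm)
        lower <- c(lower, d$x0_bounds[i, 1])
        upper <- c(upper, d$x0_bounds[i, 2])
        x0_slots[[nm]] <- list(experiment = e, state = i)
      }
    }
  }
  # per-experiment fast-path bookkeeping: output-time grid, the trajectory
  # row and observation row of every record, measured values and weights
  precomp <- purrr::map(ids, function(e) {
    d <- eff[[e]]
    sub <- dataset[dataset$experiment == e, , drop = FALSE]
    times_all <- sort(unique(c(d$t_span[1], unlist(d$sampling_times))))
    om <- d$obs_map
    linear <- !is.null(om$C)
    # records are ordered (observable, time) exactly as in the dataset
    row_idx <- match(sub$time, times_all)
    obs_idx <- match(sub$observable, om$obs_names)
    list(experiment = e, design = d, times_all = times_all,
         row_idx = row_idx, obs_idx = obs_idx, linear = linear,
         C_rec = if (linear) om$C[obs_idx, , drop = FALSE] else NULL,
         value = sub$value, sigma = sub$sigma, n_rec = nrow(sub))
  })
  names(precomp) <- ids

  structure(
    list(model = model, designs = eff, dataset = dataset,
         experiments = ids, free_names = free_names,
         lower = stats::setNames(lower, free_names),
         upper = stats::setNames(upper, free_names),
         n_free = length(free_names), x0_slots = x0_slots,
         rtol = rtol, atol = atol, guard_threshold = guard_threshold,
         precomp = precomp,
         penalty_base = max(PENALTY_FLOOR,
                            1e4 * sum((dataset$value / dataset$sigma)^2))),
    class = "mc_problem"
  )
}

#' @export
print.mc_problem <- function(x, ...) {
  cat(sprintf("<mc_problem> %d free parameter(s), %d experiment(s), %d record(s)\n",
              x$n_free, length(x$experiments), nrow(x$dataset)))
  invisible(x)
}

problem_x0 <- function(problem, experiment, phi) {
  d <- problem$designs[[experiment]]
  x0 <- d$x0
  for (nm in names(problem$x0_slots)) {
    slot <- problem$x0_slots[[nm]]
    if (slot$experiment == experiment) x0[slot$state] <- phi[[nm]]
  }
  x0
}

# blow-up penalty: finite, ordered so that earlier blow-up (a larger
# fraction of sampling points never reached) is ranked as worse, and
# guaranteed to dominate any feasible objective value by scaling with the
# trivial-prediction objective sum((ym / sigma)^2) of the dataset
PENALTY_FLOOR <- 1e10

penalty_base <- function(problem) {
  problem$penalty_base %||% PENALTY_FLOOR
}

#' Weighted least-squares cost of a parameter vector
#'
#' Evaluates the estimation objective. Blow-up or solver failure during any
#' experiment never raises: the cost degrades to a finite penalty
#' `P * (1 + fraction of unreached sampling points)` with status
#' `"blowup_abort"` (or `"solver_failure"`), so optimizers can still rank
#' such points — an earlier blow-up costs more. The base `P` is
#' `max(1e10, 1e4 * sum((ym / sigma)^2))`, which always dominates any
#' feasible objective value (the second term is the cost of predicting
#' zero everywhere), whatever the measurement-weight scale.
#'
#' @param problem An [estimation_problem()].
#' @param theta Free-parameter vector (model parameters followed by any
#'   estimated initial conditions).
#' @return A list with `J`, the vector of standardized `residuals`
#'   (`NULL` under failure) and `status` (`"ok"`, `"blowup_abort"`,
#'   `"solver_failure"`).
#' @export
wls_cost <- function(problem, theta) {
  stopifnot(inherits(problem, "mc_problem"))
  if (length(theta) != problem$n_free) {
    abort(sprintf("theta has length %d, expected %d free parameter(s)",
                  length(theta), problem$n_free))
  }
  phi <- stats::setNames(as.numeric(theta), problem$free_names)
  theta_model <- phi[seq_len(problem$model$n_theta)]
  res_all <- numeric(0)
  n_total <- nrow(problem$dataset)
  unreached <- 0
  failed <- NULL
  for (e in problem$experiments) {
    pc <- problem$precomp[[e]]
    tr <- simulate_model(problem$model, theta_model,
                         x0 = problem_x0(problem, e, phi),
                         times = pc$times_all, rtol = problem$rtol,
                         atol = problem$atol,
                         guard_threshold = problem$guard_threshold)
    status <- attr(tr, "status")
    if (status != "ok") {
      t_stop <- attr(tr, "t_stop")
      n_reached <- sum(pc$times_all[pc$row_idx] <= t_stop)
      unreached <- unreached + (pc$n_rec - n_reached)
      failed <- c(failed, if (status == "blowup") "blowup" else "failure")
      next
    }
    X <- as.matrix(tr[, -1, drop = FALSE])
    pred <- if (pc$linear) {
      rowSums(pc$C_rec * X[pc$row_idx, , drop = FALSE])
    } else {
      om <- pc$design$obs_map
      vapply(seq_len(pc$n_rec), function(k) {
        om$g(X[pc$row_idx[k], ], pc$times_all[pc$row_idx[k]])[pc$obs_idx[k]]
      }, numeric(1))
    }
    res_all <- c(res_all, (pc$value - pred) / pc$sigma)
  }
  if (!is.null(failed)) {
    frac <- unreached / max(1, n_total)
    status <- if ("blowup" %in% failed) "blowup_abort" else "solver_failure"
    return(list(J = penalty_base(problem) * (1 + frac), residuals = NULL,
                status = status))
  }
  list(J = sum(res_all^2), residuals = res_all, status = "ok")
}

# residual closure for least-squares refiners; flat penalty residuals keep
# Levenberg-Marquardt steps away from blow-up regions
problem_residual_fun <- function(problem) {
  n <- max(1, nrow(problem$dataset))
  function(phi) {
    w <- wls_cost(problem, phi)
    if (w$status != "ok") rep(sqrt(penalty_base(problem) * 2 / n), n)
    else w$residuals
  }
}

local_refine <- function(problem, start, max_iter = 100) {
  fn <- problem_residual_fun(problem)
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = start, lower = problem$lower,
                         upper = problem$upper, fn = fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ptol = 1e-10, ftol = 1e-10))),
    error = function(e) NULL
  )
  if (is.null(fit)) return(list(par = start, ok = FALSE, n_evals = 1L))
  list(par = stats::setNames(coef(fit), problem$free_names), ok = TRUE,
       n_evals = as.integer(fit$niter * (problem$n_free + 1L)))
}

#' Classify a fit against the nominal objective value
#'
#' Computes the log ratio `log10(J / J_nominal)` and classifies the fit as
#' overfitting (`"OF"`, ratio below `-delta`: the objective is materially
#' below what the true parameters achieve, i.e. noise is being fitted), a
#' good fit (`"GF"`, ratio within `delta` of zero) or a local optimum /
#' underfit (`"LO"`, ratio above `delta`).
#'
#' @param J Achieved objective value.
#' @param J_nominal Objective value at the nominal (true) parameters;
#'   must be positive. For noise-free data use the absolute criterion
#'   `J < 1e-6 * n_records` instead (see [multistart_local()]).
#' @param delta Half-width of the good-fit band on the log10 scale
#'   (default 0.25).
#' @return `"OF"`, `"GF"` or `"LO"`.
#' @export
classify_fit <- function(J, J_nominal, delta = 0.25) {
  if (!is.finite(J_nominal) || J_nominal <= 0) {
    abort("J_nominal must be positive; for noise-free data use the absolute near-zero criterion")
  }
  r <- log10(J / J_nominal)
  if (r < -delta) "OF" else if (r > delta) "LO" else "GF"
}

classify_many <- function(J, status, J_nominal, delta, n_records) {
  purrr::map2_chr(J, status, function(j, s) {
    if (s != "converged") return("failed")
    if (is.null(J_nominal) || !is.finite(J_nominal)) return(NA_character_)
    if (J_nominal <= 0) {
      if (j < 1e-6 * n_records) "GF" else "LO"
    } else classify_fit(j, J_nominal, delta)
  })
}

new_fit <- function(theta, J, status, classification = NA_character_,
                    n_obj_evals = NA_integer_, seed = NA_integer_,
                    trace = NULL, budget_exhausted = FALSE) {
  structure(
    list(theta = theta, J = J, status = status,
         classification = classification, n_obj_evals = n_obj_evals,
         seed = seed, trace = trace, budget_exhausted = budget_exhausted),
    class = "mc_fit"
  )
}

#' @export
print.mc_fit <- function(x, ...) {
  cat(sprintf("<mc_fit> status=%s, J=%.6g, evals=%s, class=%s\n",
              x$status, x$J, x$n_obj_evals, x$classification))
  invisible(x)
}

nominal_objective <- function(problem) {
  prov <- attr(problem$dataset, "provenance")
  if (is.null(prov$theta_nominal)) return(NULL)
  th <- as.numeric(prov$theta_nominal)
  if (length(th) != problem$n_free) {
    # nominal covers only the model parameters; estimated x0 unknown
    if (length(th) == problem$model$n_theta && problem$n_free > length(th)) {
      x0_true <- purrr::map_dbl(names(problem$x0_slots), function(nm) {
        slot <- problem$x0_slots[[nm]]
        problem$designs[[slot$experiment]]$x0[slot$state]
      })
      th <- c(th, x0_true)
    } else return(NULL)
  }
  w <- wls_cost(problem, th)
  if (w$status == "ok") w$J else NULL
}

#' Multistart local least-squares calibration
#'
#' Draws starting points at random within the parameter bounds and runs a
#' bound-constrained Levenberg-Marquardt refinement of the standardized
#' residual vector from each. Starts whose objective evaluation already
#' fails (blow-up or solver failure) are recorded as aborted runs, not
#' raised — mirroring how local least-squares calibration behaves on
#' blow-up-prone community models. When the dataset carries nominal-
#' parameter provenance, converged fits are classified OF/GF/LO against
#' the nominal objective value.
#'
#' @param problem An [estimation_problem()].
#' @param n_starts Number of starts.
#' @param seed Integer seed for the start sample.
#' @param sampling `"uniform"` in the box, or `"log_uniform"` (applied
#'   per-parameter where both bounds are positive).
#' @param starts Optional matrix (`n_starts x n_free`) of explicit starts,
#'   overriding the random sample.
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @param delta Good-fit half-width for OF/GF/LO classification.
#' @return An `mc_fit_ensemble`: `results` (list of `mc_fit`), a tidy
#'   per-run table `runs`, and `summary` fractions (converged, blow-up,
#'   solver failure, OF/GF/LO).
#' @export
multistart_local <- function(problem, n_starts, seed, sampling = c("uniform", "log_uniform"),
                             starts = NULL, max_iter = 100, delta = 0.25) {
  sampling <- match.arg(sampling)
  stopifnot(n_starts >= 1)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  if (is.null(starts)) {
    starts <- sample_starts(problem, n_starts, sampling)
  } else {
    starts <- matrix(starts, ncol = problem$n_free)
    n_starts <- nrow(starts)
  }
  J_nom <- nominal_objective(problem)
  n_records <- nrow(problem$dataset)

  results <- purrr::map(seq_len(n_starts), function(k) {
    phi0 <- stats::setNames(starts[k, ], problem$free_names)
    w0 <- wls_cost(problem, phi0)
    n_evals <- 1L
    if (w0$status != "ok") {
      return(new_fit(phi0, w0$J, if (w0$status == "blowup_abort")
        "blowup_abort" else "solver_failure", n_obj_evals = n_evals,
        seed = seed))
    }
    ref <- local_refine(problem, phi0, max_iter = max_iter)
    n_evals <- n_evals + ref$n_evals
    wf <- wls_cost(problem, ref$par)
    status <- if (wf$status == "ok" && ref$ok) "converged"
              else if (wf$status == "blowup_abort") "blowup_abort"
              else "solver_failure"
    new_fit(ref$par, wf$J, status, n_obj_evals = n_evals, seed = seed)
  })

  cls <- classify_many(purrr::map_dbl(results, "J"),
                       purrr::map_chr(results, "status"),
                       J_nom, delta, n_records)
  results <- purrr::map2(results, cls, function(f, cl) {
    f$classification <- cl; f
  })
  new_fit_ensemble(results, J_nominal = J_nom, delta = delta)
}

sample_starts <- function(problem, n, sampling) {
  lo <- problem$lower; up <- problem$upper
  p <- problem$n_free
  u <- matrix(stats::runif(n * p), n, p)
  starts <- sweep(sweep(u, 2, up - lo, `*`), 2, lo, `+`)
  if (sampling == "log_uniform") {
    for (j in seq_len(p)) {
      if (lo[j] > 0) {
        starts[, j] <- exp(log(lo[j]) + u[, j] * (log(up[j]) - log(lo[j])))
      }
    }
  }
  starts
}

new_fit_ensemble <- function(results, J_nominal = NULL, delta = 0.25) {
  runs <- tibble(
    run = seq_along(results),
    J = purrr::map_dbl(results, "J"),
    status = purrr::map_chr(results, "status"),
    classification = purrr::map_chr(results, "classification")
  )
  n <- nrow(runs)
  summary <- list(
    n_runs = n,
    converged = mean(runs$status == "converged"),
    blowup = mean(runs$status == "blowup_abort"),
    solver_failure = mean(runs$status == "solver_failure"),
    OF = mean(runs$classification == "OF", na.rm = TRUE),
    GF = mean(runs$classification == "GF", na.rm = TRUE),
    LO = mean(runs$classification == "LO", na.rm = TRUE),
    delta = delta, J_nominal = J_nominal
  )
  for (cl in c("OF", "GF", "LO")) {
    summary[[cl]] <- if (all(is.na(runs$classification))) NA_real_
                     else mean(runs$classification == cl, na.rm = TRUE)
  }
  structure(list(results = results, runs = runs, summary = summary),
            class = "mc_fit_ensemble")
}

#' @export
print.mc_fit_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<mc_fit_ensemble> %d runs | converged %.1f%% | ",
                     "blow-up %.1f%% | OF/GF/LO %.1f/%.1f/%.1f%%\n"),
              s$n_runs, 100 * s$converged, 100 * s$blowup,
              100 * s$OF, 100 * s$GF, 100 * s$LO))
  invisible(x)
}

#' Enhanced scatter-search settings
#'
#' @param ref_set_size Reference-set size `b`; default
#'   `max(10, ceil(1 + sqrt(n_free)))`, filled half by quality and half by
#'   diversity.
#' @param pop_size Diversification population size; default `10 * b`.
#' @param local_every Run a local Levenberg-Marquardt refinement of the
#'   best not-yet-refined member every this many iterations.
#' @param stall_limit Replace a reference member from the diversity pool
#'   after this many consecutive non-improving combinations.
#' @param max_evals Objective-evaluation budget; default `2e4 * n_free`
#'   (resolved when the problem is known).
#' @param local_max_iter Iteration cap for each local refinement.
#' @param stagnation_tol,stagnation_iters Stop when the relative
#'   improvement of the best objective over this many iterations falls
#'   below the tolerance.
#' @return A list of settings for [ess_optimize()].
#' @export
ess_settings <- function(ref_set_size = NULL, pop_size = NULL,
                         local_every = 20, stall_limit = 15,
                         max_evals = NULL, local_max_iter = 100,
                         stagnation_tol = 1e-8, stagnation_iters = 50) {
  list(ref_set_size = ref_set_size, pop_size = pop_size,
       local_every = local_every, stall_limit = stall_limit,
       max_evals = max_evals, local_max_iter = local_max_iter,
       stagnation_tol = stagnation_tol, stagnation_iters = stagnation_iters)
}

#' Enhanced scatter-search global calibration
#'
#' A population metaheuristic for the blow-up-prone, non-convex weighted
#' least-squares landscapes of community ODE models. The algorithm keeps a
#' reference set combining high-quality and maximally diverse members,
#' recombines every pair through hyper-rectangle sampling, intensifies with
#' a "go-beyond" step whenever a child improves on its parent, periodically
#' refines the best unrefined member with bound-constrained
#' Levenberg-Marquardt least squares, and replaces stalled members from a
#' fresh diversification pool. Objective evaluations that blow up receive
#' the finite ranking penalty and are never admitted to the reference set,
#' so the search can cross unstable regions without derailing.
#'
#' @param problem An [estimation_problem()].
#' @param seed Integer seed (all randomness in the run derives from it).
#' @param settings An [ess_settings()] list.
#' @param delta Good-fit half-width used for classification when nominal
#'   provenance is available.
#' @return An `mc_fit` whose `trace` tibble records the monotone
#'   best-so-far objective by iteration, with `n_obj_evals` and a
#'   `budget_exhausted` flag.
#' @export
ess_optimize <- function(problem, seed, settings = ess_settings(),
                         delta = 0.25) {
  stopifnot(inherits(problem, "mc_problem"))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  p <- problem$n_free
  lo <- problem$lower; up <- problem$upper; span <- up - lo
  b <- settings$ref_set_size %||% max(10, ceiling(1 + sqrt(p)))
  b <- max(4, as.integer(b)); if (b %% 2 == 1) b <- b + 1
  n_pop <- settings$pop_size %||% (10 * b)
  max_evals <- settings$max_evals %||% (2e4 * p)

  n_evals <- 0L
  evalJ <- function(phi) {
    n_evals <<- n_evals + 1L
    wls_cost(problem, phi)$J
  }

  # diversification: space-filling sample of the box
  pop <- sweep(sweep(lhs::randomLHS(n_pop, p), 2, span, `*`), 2, lo, `+`)
  popJ <- apply(pop, 1, evalJ)

  pb <- penalty_base(problem)
  ord <- order(popJ)
  q_idx <- ord[seq_len(min(b / 2, length(ord)))]
  rest <- setdiff(seq_len(n_pop), q_idx)
  d_idx <- diverse_subset(pop, rest, q_idx, b - length(q_idx), span)
  ref <- pop[c(q_idx, d_idx), , drop = FALSE]
  refJ <- popJ[c(q_idx, d_idx)]
  refined <- rep(FALSE, nrow(ref))
  stall <- rep(0L, nrow(ref))

  best_J <- min(refJ)
  best_phi <- ref[which.min(refJ), ]
  init_best <- min(popJ)
  trace <- list(tibble(iteration = 0L, evals = n_evals, J_best = best_J))

  pool <- sweep(sweep(lhs::randomLHS(n_pop, p), 2, span, `*`), 2, lo, `+`)
  pool_next <- 1L
  fresh_diverse <- function() {
    if (pool_next > nrow(pool)) {
      pool <<- sweep(sweep(lhs::randomLHS(n_pop, p), 2, span, `*`), 2, lo, `+`)
      pool_next <<- 1L
    }
    x <- pool[pool_next, ]; pool_next <<- pool_next + 1L
    x
  }

  iter <- 0L
  hist_best <- best_J
  while (n_evals < max_evals) {
    iter <- iter + 1L
    o <- order(refJ)
    ref <- ref[o, , drop = FALSE]; refJ <- refJ[o]
    refined <- refined[o]; stall <- stall[o]
    improved_member <- rep(FALSE, nrow(ref))

    for (i in seq_len(nrow(ref) - 1)) {
      for (j in seq((i + 1), nrow(ref))) {
        if (n_evals >= max_evals) break
        d <- (ref[j, ] - ref[i, ]) / 2
        c1 <- pmin(pmax(ref[i, ] - d, lo), up)
        c2 <- pmin(pmax(ref[i, ] + d, lo), up)
        child <- c1 + stats::runif(p) * (c2 - c1)
        Jc <- evalJ(child)
        if (Jc < refJ[i]) {
          # go-beyond intensification along the improving direction
          lambda <- 1
          repeat {
            if (n_evals >= max_evals) break
            step <- child + lambda * (child - ref[i, ])
            step <- pmin(pmax(step, lo), up)
            Js <- evalJ(step)
            if (Js < Jc) { child <- step; Jc <- Js; lambda <- 2 * lambda }
            else break
          }
          ref[i, ] <- child; refJ[i] <- Jc
          refined[i] <- FALSE; stall[i] <- 0L
          improved_member[i] <- TRUE
        } else if (Jc < max(refJ) && Jc < pb) {
          w <- which.max(refJ)
          # keep diversity: only replace if not nearly duplicating a member
          dmin <- min(sqrt(colSums((t(ref) - child)^2 / span^2)))
          if (Jc < refJ[w] && dmin > 1e-6) {
            ref[w, ] <- child; refJ[w] <- Jc
            refined[w] <- FALSE; stall[w] <- 0L
          }
        }
      }
      if (n_evals >= max_evals) break
    }
    stall[!improved_member] <- stall[!improved_member] + 1L

    # stall replacement from the diversity pool (never the incumbent best)
    for (i in which(stall >= settings$stall_limit)) {
      if (i == which.min(refJ)) next
      x <- fresh_diverse()
      ref[i, ] <- x; refJ[i] <- evalJ(x)
      refined[i] <- FALSE; stall[i] <- 0L
      if (n_evals >= max_evals) break
    }

    # periodic local refinement of the best unrefined member
    if (iter %% settings$local_every == 0 && any(!refined) &&
        n_evals < max_evals) {
      cand <- which(!refined)
      i <- cand[which.min(refJ[cand])]
      if (refJ[i] < pb) {
        lr <- local_refine(problem, stats::setNames(ref[i, ], problem$free_names),
                           max_iter = settings$local_max_iter)
        n_evals <- n_evals + lr$n_evals
        Jr <- evalJ(lr$par)
        if (Jr < refJ[i]) { ref[i, ] <- lr$par; refJ[i] <- Jr; stall[i] <- 0L }
      }
      refined[i] <- TRUE
    }

    if (min(refJ) < best_J) {
      best_J <- min(refJ); best_phi <- ref[which.min(refJ), ]
    }
    trace[[length(trace) + 1L]] <-
      tibble(iteration = iter, evals = n_evals, J_best = best_J)

    hist_best <- c(hist_best, best_J)
    if (length(hist_best) > settings$stagnation_iters) {
      w0 <- hist_best[length(hist_best) - settings$stagnation_iters]
      if ((w0 - best_J) <= settings$stagnation_tol * max(1, abs(w0))) break
    }
  }

  # final polish of the incumbent
  lr <- local_refine(problem, stats::setNames(best_phi, problem$free_names),
                     max_iter = settings$local_max_iter)
  n_evals <- n_evals + lr$n_evals
  wf <- wls_cost(problem, lr$par)
  if (wf$status == "ok" && wf$J < best_J) {
    best_phi <- lr$par; best_J <- wf$J
  }
  wfin <- wls_cost(problem, best_phi)
  status <- if (wfin$status == "ok") "converged" else wfin$status

  J_nom <- nominal_objective(problem)
  cls <- classify_many(best_J, status, J_nom, delta, nrow(problem$dataset))
  stopifnot(best_J <= init_best + 1e-12)
  new_fit(stats::setNames(best_phi, problem$free_names), best_J, status,
          classification = cls, n_obj_evals = n_evals, seed = seed,
          trace = dplyr::bind_rows(trace),
          budget_exhausted = n_evals >= max_evals)
}

# greedy max-min-distance subset (scaled coordinates) for the diversity half
diverse_subset <- function(pop, candidates, chosen, k, span) {
  if (k <= 0) return(integer(0))
  sel <- integer(0)
  scaled <- sweep(pop, 2, span, `/`)
  for (step in seq_len(min(k, length(candidates)))) {
    ref_idx <- c(chosen, sel)
    dmin <- vapply(candidates, function(i) {
      min(sqrt(rowSums((scaled[ref_idx, , drop = FALSE] -
                          matrix(scaled[i, ], length(ref_idx),
                                 ncol(pop), byrow = TRUE))^2)))
    }, numeric(1))
    pick <- candidates[which.max(dmin)]
    sel <- c(sel, pick)
    candidates <- setdiff(candidates, pick)
  }
  sel
}
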