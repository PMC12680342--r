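#' Specify a measurement-noise model
#'
#' Gaussian noise models for pseudo-experimental data: `"absolute"`
#' (constant standard deviation equal to `level`), `"proportional"`
#' (standard deviation `level * |y|` of the noise-free signal), or
#' `"mixed"` (`level * |y| + floor`). For the proportional kind the
#' standard deviation is defined from the *noise-free* signal, not the
#' noisy draw, so the weights used by the least-squares objective stay
#' consistent with the generating process. A strictly positive floor
#' avoids zero standard deviations at extinction points.
#'
#' @param kind `"absolute"`, `"proportional"` or `"mixed"`.
#' @param level Noise level: a fraction in `[0, 1]` for proportional
#'   noise, a magnitude otherwise.
#' @param floor Minimum standard deviation; `NULL` defers to
#'   `1e-6 * max(|y|)` over the design at generation time.
#' @return An `mc_noise_model`.
#' @export
noise_model <- function(kind = c("proportional", "absolute", "mixed"),
                        level = 0.1, floor = NULL) {
  kind <- match.arg(kind)
  stopifnot(level >= 0)
  if (kind == "proportional" && level > 1) {
    abort("proportional noise level must lie in [0, 1]")
  }
  if (!is.null(floor) && floor <= 0) abort("noise floor must be positive")
  structure(list(kind = kind, level = level, floor = floor),
            class = "mc_noise_model")
}

# sd of the Gaussian draw, defined from the noise-free signal
noise_draw_sd <- function(noise, y_true) {
  switch(noise$kind,
    absolute = rep(noise$level, length(y_true)),
    proportional = noise$level * abs(y_true),
    mixed = noise$level * abs(y_true) + (noise$floor %||% 0)
  )
}

# recorded per-record sigma (the objective weight): the draw sd with a
# strictly positive floor so weights stay finite at extinction points
noise_sigma <- function(noise, y_true, floor) {
  pmax(noise_draw_sd(noise, y_true), floor)
}

#' Generate a pseudo-experimental dataset
#'
#' Simulates each experiment design at the nominal parameters, samples the
#' observables on the design grids and adds Gaussian noise with per-record
#' standard deviation given by the noise model. The noise-free trajectory
#' must integrate cleanly: blow-up at the nominal parameters is an error
#' naming the failing experiment.
#'
#' @param model An [mc_model][glv_model()].
#' @param theta_nominal Nominal (ground-truth) parameter vector.
#' @param designs A list of [experiment_design()]s (or a single design).
#' @param noise An [mc_noise_model][noise_model()].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param truncate_at_zero Replace negative noisy abundances by zero.
#'   Off by default: truncation would bias the Gaussian error model the
#'   estimation objective assumes.
#' @return An `mc_dataset`: a tibble with columns `experiment`,
#'   `observable`, `time`, `value`, `sigma`, and a `provenance` attribute
#'   recording the nominal parameters, noise model and seed.
#' @export
generate_dataset <- function(model, theta_nominal, designs, noise, seed,
                             truncate_at_zero = FALSE) {
  if (inherits(designs, "mc_design")) designs <- list(designs)
  stopifnot(length(designs) >= 1, inherits(noise, "mc_noise_model"))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  rows <- purrr::map(designs, function(d) {
    pr <- predict_observables(model, theta_nominal, d)
    if (pr$status != "ok") {
      abort(sprintf("nominal simulation failed (%s) for experiment '%s'",
                    pr$status, d$experiment_id))
    }
    p <- pr$predictions
    # zero noise level: unit sigma (plain least squares) so the objective
    # of a perfect fit is numerically reachable; otherwise a small floor
    # only guards against zero sigma at extinction points
    floor <- noise$floor %||% if (noise$level == 0) 1 else
      (1e-6 * max(abs(p$value), 1e-12))
    sigma <- noise_sigma(noise, p$value, floor)
    ym <- p$value + stats::rnorm(nrow(p), 0, noise_draw_sd(noise, p$value))
    if (truncate_at_zero) ym <- pmax(ym, 0)
    tibble(experiment = d$experiment_id, observable = p$observable,
           time = p$time, value = ym, sigma = sigma, truth = p$value)
  })
  out <- dplyr::bind_rows(rows)
  new_dataset(out, provenance = list(
    model_kind = model$kind, n_x = model$n_x,
    theta_nominal = as.numeric(theta_nominal),
    param_names = model$param_names,
    noise = unclass(noise), seed = as.integer(seed),
    truncate_at_zero = truncate_at_zero
  ))
}

new_dataset <- function(tb, provenance = NULL) {
  stopifnot(all(c("experiment", "observable", "time", "value", "sigma")
                %in% names(tb)))
  if (nrow(tb) > 0 && any(tb$sigma <= 0)) abort("every record needs sigma > 0")
  tb <- dplyr::arrange(tb, .data$experiment, .data$observable, .data$time)
  structure(as_tibble(tb), provenance = provenance,
            class = c("mc_dataset", class(as_tibble(tb))))
}

# seed guard: set the RNG reproducibly and restore the caller's state
.Random.seed_guard <- function(seed) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read and write datasets
#'
#' The on-disk dialect is a plain CSV with columns `experiment`,
#' `observable`, `time`, `value`, `sigma` plus a JSON sidecar
#' (`<path>.json`) holding provenance metadata when present. The round
#' trip is lossless.
#'
#' @param dataset An `mc_dataset` (any tibble with the five columns works).
#' @param path File path for the CSV.
#' @return `read_dataset()` returns an `mc_dataset`; `write_dataset()`
#'   returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  cols <- c("experiment", "observable", "time", "value", "sigma")
  readr::write_csv(as_tibble(dataset)[, intersect(c(cols, "truth"),
                                                  names(dataset))], path)
  prov <- attr(dataset, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          experiment = readr::col_character(),
                          observable = readr::col_character()
                        ))
  cols <- c("experiment", "observable", "time", "value", "sigma")
  missing_cols <- setdiff(cols, names(tb))
  if (length(missing_cols)) {
    abort(sprintf("dataset file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  for (nc in c("time", "value", "sigma")) {
    tb[[nc]] <- suppressWarnings(as.numeric(tb[[nc]]))
  }
  bad <- which(!stats::complete.cases(tb[, cols]))
  if (length(bad)) {
    abort(sprintf("malformed dataset row(s) at line(s): %s",
                  paste(bad + 1, collapse = ", ")))
  }
  prov <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) prov <- jsonlite::read_json(side, simplifyVector = TRUE)
  new_dataset(tb, provenance = prov)
}

#' Split a dataset into training and validation parts
#'
#' Partitions records by experiment, the unit used for cross-validation on
#' held-out experiments (typically different initial conditions).
#'
#' @param dataset An `mc_dataset`.
#' @param held_out_experiments Character vector of experiment ids to hold
#'   out for validation.
#' @return A list with `training` and `validation` datasets; the two are
#'   disjoint and their union is the input.
#' @export
split_dataset <- function(dataset, held_out_experiments) {
  ids <- unique(dataset$experiment)
  unknown <- setdiff(held_out_experiments, ids)
  if (length(unknown)) {
    abort(sprintf("unknown experiment id(s): %s", paste(unknown, collapse = ", ")))
  }
  prov <- attr(dataset, "provenance")
  val <- dataset[dataset$experiment %in% held_out_experiments, , drop = FALSE]
  tr <- dataset[!dataset$experiment %in% held_out_experiments, , drop = FALSE]
  list(training = new_dataset(tr, prov), validation = new_dataset(val, prov))
}

dataset_counts <- function(dataset) {
  dplyr::summarise(dplyr::group_by(as_tibble(dataset), .data$experiment,
                                   .data$observable),
                   n_s = dplyr::n(), .groups = "drop")
}
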