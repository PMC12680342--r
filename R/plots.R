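#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_histogram
#'   geom_abline geom_vline geom_tile facet_wrap labs autoplot
#'   scale_fill_gradient2 theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' @param object An `mc_trajectory` from [simulate_model()].
#' @param dataset Optional `mc_dataset` to overlay as points (fully
#'   observed schemes).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mc_trajectory <- function(object, dataset = NULL, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
                              names_to = "state", values_to = "abundance")
  p <- ggplot(long, aes(x = .data$time, y = .data$abundance,
                        colour = .data$state)) +
    geom_line() +
    labs(title = sprintf("status: %s", attr(object, "status")),
         x = "time", y = "abundance") +
    theme_minimal()
  if (!is.null(dataset)) {
    pts <- dplyr::rename(as_tibble(dataset), state = "observable",
                         abundance = "value")
    p <- p + geom_point(data = pts, alpha = 0.6)
  }
  p
}

#' Histogram of ensemble objective values
#'
#' The x axis is `log10(J / J_nominal)`; the dashed lines mark the
#' good-fit band, separating overfitting (left), good fits (centre) and
#' local optima (right).
#'
#' @param object An `mc_fit_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mc_fit_ensemble <- function(object, ...) {
  s <- object$summary
  runs <- dplyr::filter(object$runs, .data$status == "converged")
  if (is.null(s$J_nominal) || nrow(runs) == 0) {
    return(ggplot(object$runs, aes(x = .data$status)) +
             ggplot2::geom_bar() + theme_minimal() +
             labs(x = NULL, y = "runs"))
  }
  runs$log10_ratio <- log10(runs$J / s$J_nominal)
  ggplot(runs, aes(x = .data$log10_ratio, fill = .data$classification)) +
    geom_histogram(bins = 30) +
    geom_vline(xintercept = c(-s$delta, s$delta), linetype = "dashed") +
    labs(x = expression(log[10](J / J[nominal])), y = "count") +
    theme_minimal()
}

#' Parameter-correlation heat map
#'
#' @param object An `mc_fim_report` with the correlation matrix filled in
#'   by [cramer_rao_intervals()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mc_fim_report <- function(object, ...) {
  if (is.null(object$correlation)) abort("run cramer_rao_intervals() first")
  R <- object$correlation
  long <- as_tibble(as.data.frame(as.table(R)))
  names(long) <- c("row", "col", "correlation")
  ggplot(long, aes(x = .data$col, y = .data$row, fill = .data$correlation)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Residual quantile-quantile plot
#'
#' Sorted standardized residuals against standard-normal quantiles; a
#' slope visibly below one (points compressed toward zero) is the
#' overfitting signature.
#'
#' @param residuals Numeric vector of standardized residuals, or the
#'   residual tibble accepted by [residual_diagnostics()].
#' @return A ggplot.
#' @export
plot_residual_qq <- function(residuals) {
  r <- if (is.numeric(residuals)) residuals else residuals$residual
  qq <- qq_points(r)
  ggplot(qq, aes(x = .data$theoretical, y = .data$sample)) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "theoretical quantile", y = "sample quantile") +
    theme_minimal()
}

#' Q-Q plot coordinates
#'
#' @param residuals Numeric vector of standardized residuals.
#' @return A tibble of (`theoretical`, `sample`) quantile pairs, suitable
#'   for CSV export.
#' @export
qq_points <- function(residuals) {
  r <- sort(as.numeric(residuals))
  tibble(theoretical = stats::qnorm(stats::ppoints(length(r))), sample = r)
}
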