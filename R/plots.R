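#' Plot benchmark traces
#'
#' Mean trace per algorithm with a mean±SD ribbon over repeats, faceted by
#' noise level, for either the best-found value or the distance to the true
#' optimum.
#'
#' @param object a `persbo_benchmark` result from [run_comparison()].
#' @param metric `"best_value"` or `"distance"`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.persbo_benchmark <- function(object, metric = c("best_value", "distance"),
                                      ...) {
  metric <- match.arg(metric)
  smry <- summarize_comparison(object)
  m <- paste0(metric, "_mean"); s <- paste0(metric, "_sd")
  ggplot2::ggplot(smry, ggplot2::aes(x = .data$iteration,
                                     y = .data[[m]],
                                     colour = .data$algorithm,
                                     fill = .data$algorithm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[m]] - .data[[s]],
                                      ymax = .data[[m]] + .data[[s]]),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$noise), labeller = "label_both") +
    ggplot2::labs(x = "iteration",
                  y = if (metric == "best_value") "best found value"
                      else "distance to true optimum") +
    ggplot2::theme_minimal()
}

#' Plot the predicted-best trace of a protocol run
#'
#' The best performance predicted by the GP at any parameter combination,
#' per iteration, with a ±1 posterior-SD band.
#'
#' @param object a `persbo_run` from [run_protocol()] (with `trace = TRUE`).
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.persbo_run <- function(object, ...) {
  if (is.null(object$trace)) {
    abort_persbo("run was made with trace = FALSE.", "invalid_input")
  }
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$iter, y = .data$pred_best)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pred_best - .data$pred_sigma,
                                      ymax = .data$pred_best + .data$pred_sigma),
                         fill = "pink", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "predicted best normalized performance") +
    ggplot2::theme_minimal()
}

#' Heatmap of a surrogate's posterior-mean surface at a baseline value
#'
#' The model's view of normalized performance over the frequency-current
#' grid at a fixed baseline coordinate, with the best-inferred point marked.
#'
#' @param model a fitted `persbo_gp`.
#' @param p unit-scale baseline coordinate.
#' @param space the optimization [search_space()].
#' @return a ggplot.
#' @export
plot_posterior_surface <- function(model, p, space = search_space()) {
  grid <- stim_grid(space)
  cand <- normalize_coords(grid, space)
  if (model$personalized) cand$p <- p
  post <- predict(model, cand, scale = "raw")
  df <- mutate(grid, mu = post$mu)
  best <- best_inferred(model, p, space)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$current, y = .data$frequency,
                                   fill = .data$mu)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = best, shape = 22, size = 3, colour = "red",
                        fill = NA, stroke = 1.2) +
    ggplot2::scale_fill_viridis_c(name = "predicted\nscore") +
    ggplot2::labs(x = "current (mA)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a synthetic ground-truth surface at a baseline value
#'
#' @param surface a [make_surface()] object.
#' @param p unit-scale baseline coordinate.
#' @param space a [search_space()] supplying the physical axes.
#' @return a ggplot.
#' @export
plot_surface <- function(surface, p, space = search_space()) {
  grid <- stim_grid(space)
  cand <- normalize_coords(grid, space)
  df <- mutate(grid, value = surface_value(surface, cand$x1, cand$x2, p))
  opt <- denormalize_coords(surface_optimum(surface, p), space)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$current, y = .data$frequency,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = opt, shape = 4, size = 3, colour = "red",
                        stroke = 1.2) +
    ggplot2::scale_fill_viridis_c(name = "expected\nscore") +
    ggplot2::labs(x = "current (mA)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}
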