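# ggplot2 graphics for curves and fitted objects.

#' Plot attenuation curves
#'
#' Semi-log plot of normalised signal versus b, coloured by group, one
#' facet per metabolite — the standard way attenuation data are displayed.
#'
#' @param data Curve table (see [validate_curves()]).
#' @param metabolites Optional subset of metabolites to show.
#' @return A ggplot object.
#' @export
plot_attenuation <- function(data, metabolites = NULL) {
  validate_curves(data)
  if (!is.null(metabolites)) {
    data <- dplyr::filter(data, .data$metabolite %in% metabolites)
  }
  ggplot2::ggplot(data, ggplot2::aes(.data$b, .data$signal,
                                     colour = .data$group,
                                     group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metabolite)) +
    ggplot2::labs(x = "b (ms/µm²)", y = "S(b) / S(b_min)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_microstructure Plot data and fitted sticks-and-spheres
#'   curve on a dense b grid.
#' @param object A `micro_fit`.
#' @param ... Unused.
#' @export
autoplot.micro_fit <- function(object, ...) {
  d <- object$data
  bb <- seq(min(d$b), max(d$b), length.out = 120)
  fwd <- micro_forward(object$model, object$scheme, object$fixed_f_sphere)
  line <- tibble::tibble(b = bb,
                         signal = fwd$fn(object$par[object$free], bb))
  ggplot2::ggplot(d, ggplot2::aes(.data$b, .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "b (ms/µm²)", y = "S(b)",
      title = sprintf("sticks-and-spheres fit: D_intra = %.2f, r_soma = %.1f",
                      object$par[["D_intra"]], object$par[["r_soma"]])) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_two_pool Plot the lactate data with the total two-pool
#'   fit and its intracellular and extracellular components.
#' @param object A `two_pool_fit`.
#' @param ... Unused.
#' @export
autoplot.two_pool_fit <- function(object, ...) {
  d <- object$data
  f <- object$par[["f_extra"]]
  comp <- dplyr::bind_rows(
    tibble::tibble(b = d$b, signal = object$fitted, part = "two-pool fit"),
    tibble::tibble(b = d$b, signal = f * exp(-d$b * object$par[["D_extra"]]),
                   part = "extracellular"),
    tibble::tibble(b = d$b, signal = (1 - f) * object$s_intra_lac$signal,
                   part = "intracellular"))
  ggplot2::ggplot(d, ggplot2::aes(.data$b, .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(linetype = .data$part),
                       colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "b (ms/µm²)", y = "S(b)",
                  linetype = NULL,
                  title = sprintf("two-pool lactate fit: f_extra = %.2f",
                                  f)) +
    ggplot2::theme_minimal()
}

#' @describeIn run_pipeline Dot plot of per-animal `f_extra` by group with
#'   group means.
#' @param object A `pipeline_result`.
#' @param ... Unused.
#' @export
autoplot.pipeline_result <- function(object, ...) {
  ggplot2::ggplot(object$two_pool,
                  ggplot2::aes(.data$group, .data$f_extra,
                               colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "black", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "extracellular lactate fraction f_extra") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
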