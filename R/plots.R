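#' Plot fitted dilution curves over their critical points
#'
#' @param object A `cndc_fit` from [fit_cndc()].
#' @param ... Unused.
#' @return A ggplot: critical points and the fitted `a * W^-b` curve per
#'   stratum, faceted by cut, coloured by fertilizer type.
#' @method autoplot cndc_fit
#' @export
autoplot.cndc_fit <- function(object, ...) {
  pts <- object$critical_points
  lines <- object$curves |>
    dplyr::group_by(.data$fertilizer_type, .data$cut) |>
    dplyr::reframe(w = seq(.data$w_min, .data$w_max, length.out = 50),
                   nc = .data$a * .data$w^(-.data$b))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$w_max, y = .data$nc,
                                    colour = .data$fertilizer_type)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(x = .data$w, y = .data$nc)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cut), labeller = "label_both") +
    ggplot2::labs(x = "Aboveground biomass W (t/ha)",
                  y = "Critical N concentration (%)",
                  colour = "Fertilizer") +
    ggplot2::theme_minimal()
}

#' Plot a single dilution curve
#'
#' @param object A `cndc_curve`.
#' @param ... Unused.
#' @return A ggplot of the critical points and the fitted power law.
#' @method autoplot cndc_curve
#' @export
autoplot.cndc_curve <- function(object, ...) {
  grid <- tibble::tibble(w = seq(object$w_range[1], object$w_range[2],
                                 length.out = 100))
  grid$nc <- object$a * grid$w^(-object$b)
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$w_max, y = .data$nc)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$w, y = .data$nc)) +
    ggplot2::labs(x = "Aboveground biomass W (t/ha)",
                  y = "Critical N concentration (%)") +
    ggplot2::theme_minimal()
}

#' Plot a yield response and its optimum
#'
#' @param object A `cndc_yield_fit`.
#' @param ... Unused.
#' @return A ggplot of yields against N rate with the fitted quadratic and
#'   a marker at the agronomic optimum.
#' @method autoplot cndc_yield_fit
#' @export
autoplot.cndc_yield_fit <- function(object, ...) {
  grid <- tibble::tibble(
    n_rate = seq(0, max(object$data$n_rate), length.out = 100))
  grid$yield_t_ha <- object$A * grid$n_rate^2 + object$B * grid$n_rate +
    object$C
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$n_rate, y = .data$yield_t_ha)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::annotate("point", x = object$opt_rate, y = object$max_yield,
                      shape = 4, size = 3) +
    ggplot2::labs(x = "N rate (kg/ha)", y = "Yield (t/ha)") +
    ggplot2::theme_minimal()
}

#' Plot NNI trajectories per treatment
#'
#' @param diagnostics Tibble from [diagnostic_series()].
#' @return A ggplot of NNI against sampling date per N rate, faceted by
#'   fertilizer type and cut, with the adequacy line at NNI = 1.
#' @export
plot_nni <- function(diagnostics) {
  ggplot2::ggplot(diagnostics,
                  ggplot2::aes(x = .data$date_index, y = .data$nni,
                               colour = factor(.data$n_rate))) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(ggplot2::vars(.data$fertilizer_type),
                        ggplot2::vars(.data$cut), labeller = "label_both") +
    ggplot2::labs(x = "Sampling date (index)",
                  y = "Nitrogen nutrition index",
                  colour = "N rate (kg/ha)") +
    ggplot2::theme_minimal()
}

#' Plot cumulative N deficit trajectories per treatment
#'
#' @param diagnostics Tibble from [diagnostic_series()].
#' @return A ggplot of Nand against sampling date per N rate, faceted by
#'   fertilizer type and cut, with the balance line at 0.
#' @export
plot_nand <- function(diagnostics) {
  ggplot2::ggplot(diagnostics,
                  ggplot2::aes(x = .data$date_index, y = .data$nand,
                               colour = factor(.data$n_rate))) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(ggplot2::vars(.data$fertilizer_type),
                        ggplot2::vars(.data$cut), labeller = "label_both") +
    ggplot2::labs(x = "Sampling date (index)",
                  y = "Cumulative N deficit (kg/ha)",
                  colour = "N rate (kg/ha)") +
    ggplot2::theme_minimal()
}
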