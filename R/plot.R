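#' Plot simulation operating characteristics
#'
#' `plot_power()` (also available as `autoplot()` on a `fracret_sim`
#' table) draws rejection rates against a design variable, one line per
#' method, with +/- 2 Monte Carlo standard error ribbons and the nominal
#' level as a dashed reference where null cells are present.
#'
#' @param data a `fracret_sim` tibble from [run_grid()],
#'   [simulate_gpv()] or [simulate_summary_tests()].
#' @param x variable for the horizontal axis, as a bare name; default
#'   `b_over_r`.
#' @param object a `fracret_sim` object (autoplot interface).
#' @param ... passed on to `plot_power()`.
#'
#' @return a ggplot object.
#' @export
plot_power <- function(data, x = b_over_r) {
  x <- rlang::enquo(x)
  d <- as_tibble(data)
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = !!x, y = .data$rejection_rate,
                    colour = .data$method, group = .data$method)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$rejection_rate - 2 * .data$mc_se, 0),
                   ymax = pmin(.data$rejection_rate + 2 * .data$mc_se, 1),
                   fill = .data$method),
      alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = "rejection rate", colour = "method", fill = "method") +
    ggplot2::theme_minimal()
  if (any(d$delta_true == d$delta0)) {
    p <- p + ggplot2::geom_hline(yintercept = d$alpha[1], linetype = 2)
  }
  p
}

#' @rdname plot_power
#' @export
autoplot.fracret_sim <- function(object, ...) {
  plot_power(object, ...)
}

#' @rdname plot_power
#' @export
autoplot.ni_test_result <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$p_value, y = .data$study_id,
                    colour = .data$method, shape = .data$reject)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$alpha),
                        linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "p-value (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
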