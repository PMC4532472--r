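#' Plot a time-fraction distribution
#'
#' @param object A `distribution_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distribution_estimate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$copies, y = .data$prob)) +
    ggplot2::geom_col(width = 0.9, fill = "steelblue") +
    ggplot2::labs(x = "copy number", y = "time fraction") +
    ggplot2::theme_minimal()
}

#' Plot a survival curve
#'
#' @param object A `survival_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survival_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_line(linewidth = 0.7, colour = "steelblue") +
    ggplot2::labs(x = "time", y = "P(exit time ≥ t)") +
    ggplot2::theme_minimal()
}

#' Overlay full and reduced switch distributions
#'
#' @param comparison The result of [compare_switch_models()].
#' @return A ggplot object with both distributions and the percent error in
#'   the subtitle.
#' @export
plot_switch_comparison <- function(comparison) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(comparison$dist_full), model = "full"),
    dplyr::mutate(tibble::as_tibble(comparison$dist_reduced),
                  model = "reduced")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$copies, y = .data$prob,
                                   colour = .data$model)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Clb2 copy number", y = "time fraction",
                  subtitle = sprintf("density error %.3g%%",
                                     comparison$error_pct)) +
    ggplot2::theme_minimal()
}

#' Plot relaxation time against the mean slow-reaction interval
#'
#' @param curve The tibble from [relaxation_vs_firing_curve()], or several
#'   row-bound together with an extra grouping column `k`.
#' @return A ggplot object on a log y-scale.
#' @export
plot_relaxation_curve <- function(curve) {
  df <- tidyr::pivot_longer(curve, c("t_relax", "slow_interval"),
                            names_to = "quantity", values_to = "time")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$clb2, y = .data$time,
                                   linetype = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Clb2 copy number", y = "time") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
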