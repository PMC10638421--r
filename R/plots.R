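# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pulse-triggered average
#'
#' Spike probability per 0.5-ms bin over the inter-pulse interval, with the
#' masked (blanked) bins shaded.
#'
#' @param object A [compute_pta()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pta_profile <- function(object, ...) {
  bw <- attr(object, "bin_ms")
  blank_end <- max(object$t_lo_ms[!object$valid]) + bw
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$t_lo_ms + bw / 2, y = .data$prob)) +
    ggplot2::annotate("rect", xmin = 0, xmax = blank_end, ymin = -Inf,
                      ymax = Inf, alpha = 0.2, fill = "grey40") +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::facet_wrap(~channel_id) +
    ggplot2::labs(x = "time after pulse (ms)", y = "spike probability") +
    ggplot2::theme_minimal()
}

#' Prevalence of ICMS-evoked modulation over the motor array
#'
#' @param prevalence Output of [summarize_prevalence()].
#' @return A ggplot of the array grid; unwired electrodes in grey.
#' @export
plot_prevalence_map <- function(prevalence) {
  ggplot2::ggplot(prevalence,
                  ggplot2::aes(x = .data$grid_col, y = .data$grid_row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$prop_modulating),
                       color = "white") +
    ggplot2::geom_tile(data = dplyr::filter(prevalence, !.data$wired),
                       fill = "grey70", color = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA), name = "prop.") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Proportion of stimulating channels modulating each motor channel") +
    ggplot2::theme_minimal()
}

#' Digit map over the motor array
#'
#' @param map A `digit_map` (motor or projection).
#' @param arraymap Array map for grid coordinates.
#' @return A ggplot faceted by digit.
#' @export
plot_digit_map <- function(map, arraymap) {
  m1 <- dplyr::filter(arraymap, .data$region == "M1", .data$wired)
  d <- dplyr::left_join(
    map, dplyr::select(m1, channel_id = "electrode_id", "grid_row",
                       "grid_col"),
    by = "channel_id"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$grid_col, y = .data$grid_row,
                                  fill = .data$value)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::facet_wrap(~digit, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", name = "modulation") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste(attr(map, "source"), "map")) +
    ggplot2::theme_minimal()
}

#' Closed-loop outcome distributions
#'
#' Transport path lengths by feedback condition.
#'
#' @param outcomes Outcome tibble from [run_closed_loop()].
#' @return A ggplot.
#' @export
plot_outcomes <- function(outcomes) {
  ggplot2::ggplot(outcomes,
                  ggplot2::aes(x = .data$condition, y = .data$path_length_m,
                               fill = .data$condition)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = "transport path length (m)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
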