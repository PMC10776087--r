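# ggplot2 views of the phase analysis.

#' Linear phase plot with the control variability band
#'
#' Transformed phases per timepoint, drawn as jittered points over the shaded
#' control band (center +/- 2 SD): the standard linear rendering of circular
#' phase data, with irregular steps falling outside the band and dorsal-step
#' points highlighted.
#'
#' @param phases Classified phase points for one pair
#'   ([classify_irregular()] output).
#' @param bounds The matching [control_bounds()] row.
#' @return A ggplot object.
#' @export
plot_phase_linear <- function(phases, bounds) {
  stopifnot(nrow(bounds) == 1)
  ggplot2::ggplot(phases,
                  ggplot2::aes(x = .data$timepoint,
                               y = .data$transformed_phase)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = max(0, bounds$center - bounds$half_width),
                      ymax = min(1, bounds$center + bounds$half_width),
                      alpha = 0.15, fill = "#2166ac") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$irregular,
                                      shape = .data$dorsal),
                         width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#b2182b")) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "transformed phase (cycles)", x = NULL,
                  colour = "irregular", shape = "dorsal",
                  subtitle = paste0(unique(phases$pair), " pair")) +
    ggplot2::theme_minimal()
}

#' Circular phase plot
#'
#' Phase points on the unit circle (0/1 synchrony at the top, 0.5 alternation
#' at the bottom), faceted by timepoint.
#'
#' @param phases Phase points with `phi` and `timepoint`.
#' @return A ggplot object.
#' @export
plot_phase_circular <- function(phases) {
  ggplot2::ggplot(phases, ggplot2::aes(x = .data$phi, y = 1)) +
    ggplot2::geom_jitter(height = 0.08, width = 0, alpha = 0.6,
                         ggplot2::aes(colour = .data$timepoint)) +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 1),
                                breaks = c(0, 0.25, 0.5, 0.75)) +
    ggplot2::scale_y_continuous(limits = c(0, 1.2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = "phase (cycles)", y = NULL)
}

#' Phase-phase coupling plot
#'
#' Plots one limb pair's phase against another's per lead stride, the
#' representation used to examine which pair-phase combinations co-occur.
#'
#' @param coupling A [pair_coupling_table()] output.
#' @param x,y Pair columns to plot (tidy-eval), e.g. `hindlimb`, `forelimb`.
#' @return A ggplot object.
#' @export
plot_pair_coupling <- function(coupling, x, y) {
  ggplot2::ggplot(coupling, ggplot2::aes(x = {{ x }}, y = {{ y }})) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::theme_minimal()
}
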