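# ggplot2 figure helpers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Volume curves of the VZ and combined VZ/SVZ over embryonic time, the
#' standard view of a simulation run.
#'
#' @param object A `niche_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot niche_trajectory
#' @export
autoplot.niche_trajectory <- function(object, ...) {
  obs <- object$observables |>
    dplyr::select(dplyr::all_of(c("time", "V_VZ", "V_combined"))) |>
    tidyr::pivot_longer(-dplyr::all_of("time"),
                        names_to = "compartment", values_to = "volume")
  ggplot2::ggplot(obs, ggplot2::aes(.data$time, .data$volume,
                                    colour = .data$compartment)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "embryonic day", y = "volume (model units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a genotype comparison
#'
#' @param comparison Output of [simulate_comparison()].
#' @param what Observable column to plot (default `"V_combined"`).
#' @return A ggplot of the observable over time, coloured by genotype.
#' @export
plot_comparison <- function(comparison, what = "V_combined") {
  if (!what %in% names(comparison)) abort_usage("unknown observable column")
  ggplot2::ggplot(comparison,
                  ggplot2::aes(.data$time, .data[[what]],
                               colour = .data$genotype)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "embryonic day", y = what, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the candidate growth hypotheses
#'
#' Draws the canonical curve of each growth family over a time window, the
#' schematic family portrait behind the exclusion argument.
#'
#' @param times Days to evaluate (default E13.5 to E17.5).
#' @param specs Optional named list of [growth_curve_spec()] objects; by
#'   default one canonical member per family.
#' @return A ggplot.
#' @export
plot_hypotheses <- function(times = seq(13.5, 17.5, by = 0.05), specs = NULL) {
  if (is.null(specs)) {
    specs <- list(
      growth_curve_spec("logistic", r = log(5)),
      growth_curve_spec("rapid_cycle", r = log(5)),
      growth_curve_spec("lag_logistic", r = log(5), t_lag = 1),
      growth_curve_spec("linear", c = 0.5),
      growth_curve_spec("delayed_logistic", r = log(5), t_delay = 1)
    )
  }
  curves <- purrr::list_rbind(purrr::map(specs, growth_curve, times = times))
  ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$volume,
                                       colour = .data$family)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "embryonic day", y = "volume (model units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
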