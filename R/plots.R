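# ggplot2 convenience plots for the three result types.

#' Plot a dose-response curve
#'
#' @param object a `mito_curve` tibble from [population_dose_response()]
#'   (several stacked conditions/protocols are fine).
#' @param ... unused.
#' @return A ggplot object: fraction mitotic vs dose (log10 x for positive
#'   doses), coloured by protocol, faceted by condition.
#' @export
autoplot.mito_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$dose_uM,
                               y = .data$fraction_mitotic,
                               colour = .data$protocol)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "1NM-PP1 (uM)", y = "fraction mitotic at endpoint") +
    ggplot2::theme_minimal()
}

#' Plot signal-response branches
#'
#' @param object a `mito_branch` tibble from [sweep_signal_response()]
#'   (stack the up and down sweeps to see the hysteresis loop).
#' @param ... unused.
#' @return A ggplot object: steady-state substrate phosphorylation fraction
#'   vs dose, one line per sweep direction.
#' @export
autoplot.mito_branch <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$dose_uM, y = .data$sub_frac,
                               colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "1NM-PP1 (uM)",
                  y = "steady-state Subp / SubTot") +
    ggplot2::theme_minimal()
}

#' Plot a trajectory
#'
#' @param object a `mito_trajectory` tibble from [simulate_model()].
#' @param variables state variables to show.
#' @param ... unused.
#' @return A ggplot object of concentration vs time.
#' @export
autoplot.mito_trajectory <- function(object,
                                     variables = c("Subp", "CycBCdk1",
                                                   "PP2AB55", "Gwlp"),
                                     ...) {
  long <- tidyr::pivot_longer(object, dplyr::all_of(variables),
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "concentration (AU)") +
    ggplot2::theme_minimal()
}
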