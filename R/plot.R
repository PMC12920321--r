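#' Plot weekly KPI series of a simulation run
#'
#' Faceted weekly series: surgeries, alternatives, reschedules, machine
#' charges, trays cleaned and time-average queue lengths. Useful for
#' eyeballing the warm-up transient before running [mser()].
#'
#' @param object A `css_sim_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.css_sim_result <- function(object, ...) {
  long <- object$weekly |>
    tidyr::pivot_longer(-"week", names_to = "kpi", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$week, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~kpi, scales = "free_y") +
    ggplot2::labs(x = "week", y = NULL,
                  title = "Weekly tray-cycle KPIs") +
    ggplot2::theme_minimal()
}

#' Plot a policy comparison
#'
#' Total inventory against reschedule and alternative-tray percentages,
#' one point per policy, with replication half-width error bars.
#'
#' @param object A `css_comparison` from [compare_policies()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.css_comparison <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("reschedule_pct", "alternative_pct"),
                        names_to = "kpi", values_to = "value") |>
    dplyr::mutate(hw = ifelse(.data$kpi == "reschedule_pct",
                              .data$reschedule_hw, .data$alternative_hw))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$total_inventory,
                                     y = .data$value,
                                     label = .data$policy)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$hw,
                                          ymax = .data$value + .data$hw),
                             colour = "steelblue") +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::facet_wrap(~kpi, scales = "free_y") +
    ggplot2::labs(x = "total tray inventory", y = "percent of surgeries") +
    ggplot2::theme_minimal()
}

#' Plot the MSER statistic over candidate truncations
#'
#' @param object An `mser_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mser_result <- function(object, ...) {
  ggplot2::ggplot(object$statistics,
                  ggplot2::aes(x = .data$d, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = object$statistics[
      object$statistics$d == object$d_star, ],
      colour = "firebrick", size = 2) +
    ggplot2::labs(x = "truncation d (batches)",
                  y = "marginal standard-error statistic",
                  title = sprintf("MSER-%d: d* = %d", object$m, object$d_star)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
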