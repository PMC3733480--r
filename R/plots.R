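#' Caterpillar plot of rank credible intervals
#'
#' Counties ordered by point rank on the x axis, posterior rank on the y
#' axis: the point rank with its central credible interval, colored by
#' quartile certainty. The characteristic funnel -- wide intervals in the
#' middle of the league table, narrow at the extremes -- is the main visual
#' message.
#'
#' @param object A `rank_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rank_summary
#' @export
autoplot.rank_summary <- function(object, ...) {
  lvl <- attr(object, "level") %||% 0.9
  ggplot2::ggplot(object, ggplot2::aes(x = .data$point_rank,
                                       y = .data$point_rank)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci_low,
                                         ymax = .data$ci_high,
                                         color = .data$high_certainty),
                            alpha = 0.6) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
      name = "quartile\ncertainty",
      labels = c(`TRUE` = "high (P ≥ 0.8)", `FALSE` = "low")) +
    ggplot2::labs(x = "point rank (1 = healthiest)",
                  y = sprintf("posterior rank (%d%% credible interval)",
                              round(100 * lvl))) +
    ggplot2::theme_minimal()
}

#' Plot rank-interval width against county population
#'
#' @param summary A `rank_summary`.
#' @param universe The matching universe (for populations).
#' @return A ggplot of percentile CI width vs log10 population.
#' @export
plot_width_vs_population <- function(summary, universe) {
  df <- summary %>%
    left_join(select(universe$geography, "county_id", "population"),
              by = "county_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population,
                                   y = .data$percentile_ci_width)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "county population (log scale)",
                  y = "90% rank CI width (percentile ranks)") +
    ggplot2::theme_minimal()
}

#' Histogram of replicate IQRs against the observed IQR
#'
#' @param object A `ppc_result` (one measure).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ppc_result
#' @export
autoplot.ppc_result <- function(object, ...) {
  reps <- tibble(iqr = attr(object, "replicate_iqrs"))
  ggplot2::ggplot(reps, ggplot2::aes(x = .data$iqr)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_iqr,
                        color = "#b2182b", linewidth = 1) +
    ggplot2::labs(
      x = "across-county IQR of replicate datasets",
      y = "replicates",
      title = paste0(object$measure, ": posterior predictive P = ",
                     signif(object$ppp_value, 3))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
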