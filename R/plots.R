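#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_ribbon scale_fill_gradient2 labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a robustness curve
#'
#' Mean Spearman rho against removal fraction, with a ribbon spanning one
#' standard deviation across replicates.
#'
#' @param object A `robustness_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.robustness_curve <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$fraction, y = .data$mean_rho)) +
    geom_ribbon(aes(ymin = .data$mean_rho - .data$sd_rho,
                    ymax = .data$mean_rho + .data$sd_rho), alpha = 0.2) +
    geom_line() + geom_point() +
    labs(
      x = "fraction of edges removed",
      y = "mean Spearman ρ (intact vs reduced ranking)",
      title = sprintf("%s / %s on %s", attr(object, "method"),
                      attr(object, "measure"), attr(object, "network"))
    ) +
    theme_minimal()
}

#' Heatmap of mean rank correlations
#'
#' One tile per (network x method, measure) cell at a single removal
#' fraction — the aggregated output of [robustness_matrix()].
#'
#' @param summary Tibble from [robustness_matrix()] or
#'   [summarise_robustness()].
#' @return A ggplot object.
#' @export
plot_robustness_heatmap <- function(summary) {
  summary$row <- interaction(summary$network, summary$method, sep = " / ")
  ggplot(summary, aes(x = .data$measure, y = .data$row, fill = .data$mean_rho)) +
    geom_tile() +
    scale_fill_gradient2(low = "#b2182b", mid = "#f7f7f7", high = "#2166ac",
                         midpoint = 0.5, limits = c(-1, 1), name = "mean ρ") +
    labs(x = "centrality measure", y = "network / removal method") +
    theme_minimal()
}

#' Plot a stability profile
#'
#' Mean rank against rank variability per node; stable nodes (rank
#' standard deviation strictly below the percentile threshold) are
#' highlighted.
#'
#' @param object A `stability_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_profile <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$mean_rank, y = .data$rank_std, colour = .data$stable)) +
    geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "#1b9e77")) +
    labs(x = "average rank across removal levels",
         y = "rank standard deviation",
         colour = "stable") +
    theme_minimal()
}
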