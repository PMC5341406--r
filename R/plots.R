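#' Plot per-cell trajectories of one or more clones
#'
#' @param trajectories long-format trajectory tibble.
#' @param colour_by column mapped to colour (e.g. `"fate"`).
#' @param clones optional subset of clone ids.
#' @return a ggplot object.
#' @export
plot_trajectories <- function(trajectories, colour_by = "fate",
                              clones = NULL) {
  if (!is.null(clones))
    trajectories <- filter(trajectories, .data$clone_id %in% clones)
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(.data$time_h, .data$yfp,
                               group = interaction(.data$clone_id, .data$cell_id),
                               colour = .data[[colour_by]])) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$clone_id), scales = "free_y") +
    ggplot2::labs(x = "time after drug (h)", y = "YFP level (a.u.)") +
    ggplot2::theme_minimal()
}

#' Histogram of per-cell central slopes for one clone
#'
#' Mirrors the slope-distribution view used to display bimodal clones:
#' per-cell central slopes over the analysis window, filled by fate.
#'
#' @param trajectories long-format trajectory tibble.
#' @param clone clone id to plot.
#' @param config an [analysis_config()].
#' @return a ggplot object.
#' @export
plot_slope_histogram <- function(trajectories, clone,
                                 config = analysis_config()) {
  s <- slope_summaries(filter(trajectories, .data$clone_id == clone), config)
  s <- filter(s, .data$usable)
  ggplot2::ggplot(s, ggplot2::aes(.data$central_slope, fill = .data$fate)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "central slope (fluorescence/h)", y = "cells",
                  title = clone) +
    ggplot2::theme_minimal()
}

#' Clustered, z-scored dynamics heatmap
#'
#' @param trajectories long-format trajectory tibble.
#' @return a ggplot object (tile heatmap, rows in cluster order).
#' @export
plot_dynamics_heatmap <- function(trajectories) {
  m <- mean_dynamics(trajectories)
  z <- normalize_dynamics_matrix(m)
  ord <- cluster_order(z)
  df <- as_tibble(z, .name_repair = "minimal")
  df$clone_id <- rownames(z)
  long <- tidyr::pivot_longer(df, -"clone_id", names_to = "time_h",
                              values_to = "z")
  long$time_h <- as.numeric(long$time_h)
  long$clone_id <- factor(long$clone_id, levels = rownames(z)[rev(ord)])
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$clone_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "time after drug (h)", y = NULL,
                  fill = "z-scored\nmean level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano-style overview of a bimodality screen
#'
#' Plots each eligible clone's smallest raw p-value against the imbalance of
#' its sign groups, highlighting bimodal calls.
#'
#' @param object a `bimodal_screen`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bimodal_screen <- function(object, ...) {
  d <- tidy(object)
  d <- filter(d, .data$eligible)
  d$min_p <- pmin(d$p_t, d$p_ks, d$p_mw)
  d$balance <- d$n_pos / (d$n_pos + d$n_neg)
  ggplot2::ggplot(d, ggplot2::aes(.data$balance, -log10(pmax(.data$min_p, 1e-300)),
                                  colour = .data$is_bimodal)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of cells with positive slope",
                  y = "-log10 min p (3 tests)", colour = "bimodal") +
    ggplot2::theme_minimal()
}
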