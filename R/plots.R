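#' Heatmap of a MIND network
#'
#' Tiles the symmetric edge-weight matrix, optionally ordering nodes by a
#' parcellation's system blocks.
#'
#' @param object A `mind_network`.
#' @param parcellation Optional [parcellation()]; nodes are ordered by
#'   system.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mind_network
#' @export
autoplot.mind_network <- function(object, parcellation = NULL, ...) {
  w <- as.matrix(object)
  nodes <- object$nodes
  if (!is.null(parcellation)) {
    ord <- parcellation$region_id[order(parcellation$system_id)]
    nodes <- intersect(ord, nodes)
    w <- w[nodes, nodes]
  }
  df <- tidyr::expand_grid(region_a = nodes, region_b = nodes)
  df$weight <- as.vector(t(w))
  df$region_a <- factor(df$region_a, levels = nodes)
  df$region_b <- factor(df$region_b, levels = rev(nodes))
  ggplot2::ggplot(df, ggplot2::aes(.data$region_a, .data$region_b,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "w", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Null distribution of a permutation test with the observed value
#'
#' @param object A `permutation_result` (with nulls recomputable from its
#'   summaries this plot shows the normal approximation band; supply
#'   `nulls` for the raw histogram).
#' @param nulls Optional numeric vector of null statistics to histogram.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, nulls = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(nulls)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(x = nulls),
      ggplot2::aes(.data$x), bins = 40, fill = "grey70", colour = "grey40")
  } else {
    xs <- seq(object$null_mean - 4 * object$null_sd,
              object$null_mean + 4 * object$null_sd, length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(x = xs,
                            y = stats::dnorm(xs, object$null_mean,
                                             object$null_sd)),
      ggplot2::aes(.data$x, .data$y), colour = "grey40")
  }
  p + ggplot2::geom_vline(xintercept = object$observed, colour = "#7a1f2b",
                          linewidth = 1) +
    ggplot2::labs(x = "statistic", y = NULL,
                  subtitle = sprintf("z = %.2f, p = %.2g (%d nulls)",
                                     object$z, object$p, object$n_nulls)) +
    ggplot2::theme_minimal()
}

#' Intraclass-edge percentage across density thresholds
#'
#' @param curve Tibble from [intraclass_edge_curve()].
#' @param null_curves Optional list of curves from null networks; their
#'   per-density mean is drawn as a reference line.
#' @return A ggplot.
#' @export
plot_intraclass_curve <- function(curve, null_curves = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(100 * .data$density,
                                           .data$pct_intraclass)) +
    ggplot2::geom_line(colour = "#7a1f2b", linewidth = 1) +
    ggplot2::geom_point(colour = "#7a1f2b") +
    ggplot2::labs(x = "network density (%)", y = "intraclass edges (%)") +
    ggplot2::theme_minimal()
  if (!is.null(null_curves)) {
    nm <- dplyr::summarise(
      dplyr::group_by(dplyr::bind_rows(null_curves), .data$density),
      pct_intraclass = mean(.data$pct_intraclass), .groups = "drop")
    p <- p + ggplot2::geom_line(data = nm, colour = "grey50",
                                linetype = "dashed")
  }
  p
}

#' Strength trajectories across timepoints
#'
#' @param observations Tibble from [strength_observations()].
#' @return A ggplot of per-region strength against age.
#' @export
plot_strength_trajectories <- function(observations) {
  ggplot2::ggplot(observations,
                  ggplot2::aes(.data$age_pnd, .data$value,
                               group = interaction(.data$unit,
                                                   .data$subject))) +
    ggplot2::geom_line(alpha = 0.15) +
    ggplot2::stat_summary(ggplot2::aes(group = NULL), fun = median,
                          geom = "line", colour = "#7a1f2b", linewidth = 1) +
    ggplot2::labs(x = "age (postnatal days)", y = "nodal strength") +
    ggplot2::theme_minimal()
}
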