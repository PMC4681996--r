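#' Plot per-country trial densities by group
#'
#' Dot plot of trials per million inhabitants on a log axis, grouped by
#' income group or region; only eligible countries (population above the
#' reporting threshold) are drawn.
#'
#' @param densities Output of [density_table()].
#' @param by Grouping column: `"income_group"` or `"region"`.
#' @return A ggplot object.
#' @export
plot_density <- function(densities, by = c("income_group", "region")) {
  by <- match.arg(by)
  d <- dplyr::filter(densities, .data$eligible, .data$density > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[by]], y = .data$density)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "trials per million inhabitants") +
    ggplot2::theme_minimal()
}

#' Plot annual location shares over time
#'
#' Stacked-area chart of the share of country locations per region or
#' income group and year.
#'
#' @param annual Output of [annual_distribution()].
#' @return A ggplot object.
#' @export
plot_annual_shares <- function(annual) {
  group_col <- setdiff(names(annual), c("year", "n_locations", "share"))[1]
  ggplot2::ggplot(annual, ggplot2::aes(x = .data$year, y = .data$share,
                                       fill = .data[[group_col]])) +
    ggplot2::geom_area() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "share of trial locations", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a co-occurrence network with its clusters
#'
#' Draws the overrepresentation network with edge width proportional to the
#' degree of overrepresentation and nodes coloured by cluster when a
#' partition is supplied.
#'
#' @param edges Edge tibble from [build_cooccurrence_network()] (or any
#'   weighted edge tibble).
#' @param partition Optional `trial_partition` for node colours.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_cooccurrence <- function(edges, partition = NULL, seed = 1L) {
  g <- as_collab_graph(edges)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(node = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  el <- igraph::as_data_frame(g)
  seg <- dplyr::left_join(el, nodes, by = c(from = "node")) |>
    dplyr::left_join(nodes, by = c(to = "node"), suffix = c("", "end"))
  if (!is.null(partition)) {
    nodes$cluster <- factor(partition$membership[nodes$node])
  } else {
    nodes$cluster <- factor(1)
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          colour = "grey60", alpha = 0.6) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$cluster), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "cluster", linewidth = "degree")
}
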