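#' Plot the degree distributions of a contrast subgraph
#'
#' Side-by-side boxplots (with jittered points) of the subgraph nodes'
#' weighted degrees in the two networks, annotated with the Mann-Whitney
#' p-value — a strong contrast subgraph shows clearly separated
#' distributions.
#'
#' @param x A `degree_test` from [degree_distribution_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.degree_test <- function(x, ...) {
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network, y = .data$degree,
                                   fill = .data$network)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.5) +
    ggplot2::labs(
      x = "network", y = "weighted degree in subgraph",
      subtitle = sprintf("Mann-Whitney p = %.3g (%s)", x$p_value, x$method)
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.degree_test
#' @export
plot_degree_distribution <- function(x, ...) autoplot.degree_test(x, ...)

#' Dotplot of an enrichment table
#'
#' The conventional over-representation dotplot: gene ratio on the x axis,
#' sets on the y axis ordered by adjusted p, dot size = overlap count,
#' color = adjusted p.
#'
#' @param x An `enrichment_tbl` from [enrich()].
#' @param top Number of top sets to show (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_tbl <- function(x, top = 10, ...) {
  df <- utils::head(tibble::as_tibble(x), top)
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_ratio, y = .data$set,
                                   size = .data$overlap, color = .data$p_adjust)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient(low = "red", high = "blue") +
    ggplot2::labs(x = "gene ratio", y = NULL, size = "overlap",
                  color = "adjusted p") +
    ggplot2::theme_minimal()
}

#' Plot a peel trace
#'
#' Objective value of every candidate subgraph against its size, with the
#' returned maximum highlighted.
#'
#' @param x A `greedy_peel` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.greedy_peel <- function(x, ...) {
  df <- x$trace
  best <- df[x$argmax_iteration, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$objective)) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point(data = best, color = "red", size = 2) +
    ggplot2::labs(x = "candidate size |H|", y = "density objective f(H)",
                  subtitle = sprintf("C = %g; best f = %.4g at |S| = %d",
                                     x$c_value, x$objective, length(x$node_set))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
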