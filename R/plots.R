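#' Plot observed vs permutation-expected profile counts
#'
#' Side-by-side bars of assigned and expected gene counts per model profile,
#' with significant profiles highlighted.
#'
#' @param object a `profile_stats` tibble.
#' @param alpha significance level used for highlighting.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.profile_stats <- function(object, alpha = 0.05, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(label = paste0(.data$profile, " ", .data$shape),
                  significant = .data$p < alpha) |>
    tidyr::pivot_longer(c("assigned", "expected"),
                        names_to = "kind", values_to = "count")
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$label, .data$profile),
                                    y = .data$count, fill = .data$kind,
                                    alpha = .data$significant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4), guide = "none") +
    ggplot2::labs(x = "model profile", y = "genes", fill = NULL) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot enrichment results as a -log10(p) bar chart
#'
#' @param object an `enrichment_result` tibble (ideally after
#'   [filter_enriched()]).
#' @param top show at most this many categories (by ascending p).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::arrange(.data$p) |>
    head(top) |>
    dplyr::mutate(neg_log10_p = -log10(.data$p))
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$category, .data$neg_log10_p),
                                    y = .data$neg_log10_p)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' Plot a gene network with node size proportional to betweenness
#'
#' @param object a `gene_network`.
#' @param ... unused.
#' @return A ggplot object (nodes laid out by igraph's Fruchterman-Reingold).
#' @export
autoplot.gene_network <- function(object, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  g <- igraph::graph_from_data_frame(object$edges[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = object$nodes$gene)
  set.seed(1)  # layout only; analysis results never depend on it
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  seg <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, "gene", x0 = "x", y0 = "y"),
                     by = c(source = "gene")) |>
    dplyr::left_join(dplyr::select(nodes, "gene", x1 = "x", y1 = "y"),
                     by = c(target = "gene"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          color = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, size = .data$bc),
                        color = "firebrick") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
                       vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "betweenness")
}
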