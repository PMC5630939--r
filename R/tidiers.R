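# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a knowledge assembly model
#'
#' @param x A `kam`.
#' @param ... Unused.
#' @return The edge table as a tibble: `source`, `target`, `relation`,
#'   `causal`, `structural`, `evidence_count`.
#' @export
tidy.kam <- function(x, ...) {
  x$edges[, c("source", "target", "relation", "causal", "structural",
              "evidence_count")]
}

#' One-row summary of a knowledge assembly model
#'
#' @param x A `kam`.
#' @param ... Unused.
#' @return A one-row tibble: node/edge counts, causal and non-causal edge
#'   counts, total supporting evidence and source-document count.
#' @export
glance.kam <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_causal = sum(x$edges$causal),
         n_non_causal = sum(!x$edges$causal),
         n_evidence = sum(x$edges$evidence_count),
         n_documents = length(x$provenance))
}

#' @rdname tidy.kam
#' @export
tidy.degree_report <- function(x, ...) x$degrees

#' @rdname glance.kam
#' @export
glance.degree_report <- function(x, ...) {
  tibble(n_nodes = nrow(x$degrees), n_edges = x$n_edges,
         mean_degree = x$mean_degree,
         max_degree = if (nrow(x$degrees)) max(x$degrees$degree) else NA_integer_)
}

#' Plot a degree distribution on log-log axes
#'
#' @param object A `degree_report`.
#' @param ... Unused.
#' @return A ggplot: log10 frequency against log10 degree, with the mean
#'   degree (the hub threshold) as a dashed line.
#' @export
autoplot.degree_report <- function(object, ...) {
  h <- object$histogram[object$histogram$degree >= 1L, , drop = FALSE]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$degree, y = .data$n)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_vline(xintercept = max(object$mean_degree, 1e-9),
                        linetype = "dashed") +
    ggplot2::labs(x = "degree", y = "number of nodes",
                  title = "Degree distribution",
                  subtitle = sprintf("mean degree %.2f (hub threshold)",
                                     object$mean_degree))
}

#' Plot the node census of a KAM
#'
#' @param k A `kam`.
#' @return A ggplot bar chart of node counts per BEL function.
#' @export
plot_node_census <- function(k) {
  cen <- node_census(k)
  cen <- cen[cen$n > 0L, , drop = FALSE]
  ggplot2::ggplot(cen, ggplot2::aes(x = stats::reorder(.data$long, .data$n),
                                    y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "nodes", title = "Node census by BEL function")
}
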