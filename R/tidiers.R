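#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-iteration trace of a run
#'
#' @param x An `amend_run`.
#' @param ... Unused.
#' @return The trace as a tibble, one row per iteration (`iteration`,
#'   `n_nodes`, `n_edges`, `score`, `alpha`, `filtering_rate`, `mean_z`,
#'   `mean_ccc`), without the list-column of node sets.
#' @export
tidy.amend_run <- function(x, ...) {
  dplyr::select(x$trace, -"nodes")
}

#' One-row summary of a run
#'
#' @param x An `amend_run`.
#' @param ... Unused.
#' @return A one-row tibble: module size, edge count, score, the
#'   iteration it came from, its restart value, the schedule parameters
#'   and the number of iterations executed.
#' @export
glance.amend_run <- function(x, ...) {
  m <- x$module
  tibble::tibble(
    n_nodes = length(m$nodes),
    n_edges = igraph::ecount(m$graph),
    score = m$score,
    iteration = m$iteration,
    alpha = m$alpha,
    eta0 = x$eta0,
    decay = x$decay,
    n_iterations = nrow(x$trace)
  )
}

#' Plot the trajectory of a run
#'
#' Network size, module score, mean standardized ECI and filtering rate
#' against iteration, with the iteration of the returned module marked.
#'
#' @param object An `amend_run`.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.amend_run <- function(object, ...) {
  tr <- tidy(object)
  long <- tidyr::pivot_longer(
    dplyr::select(tr, "iteration", "n_nodes", "score", "mean_z", "filtering_rate"),
    -"iteration", names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$module$iteration,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "Module identification trajectory",
                  subtitle = "dashed line: iteration of the returned module") +
    ggplot2::theme_minimal()
}

#' Plot a module coloured by ECI
#'
#' A simple force-directed drawing of the module, nodes shaded by ECI.
#'
#' @param run An `amend_run`.
#' @param stats Gene statistics table supplying ECIs.
#' @return A `ggplot` object.
#' @export
plot_module <- function(run, stats) {
  g <- run$module$graph
  set.seed(1L)  # layout only; does not affect any analysis result
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(
    gene_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
    eci = stats$eci[match(igraph::V(g)$name, stats$gene_id)]
  )
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(
    x = nodes$x[match(el[, 1], nodes$gene_id)],
    y = nodes$y[match(el[, 1], nodes$gene_id)],
    xend = nodes$x[match(el[, 2], nodes$gene_id)],
    yend = nodes$y[match(el[, 2], nodes$gene_id)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, fill = .data$eci),
                        shape = 21, size = 5) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene_id),
                       vjust = -1.2, size = 2.8) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac") +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "ECI")
}
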