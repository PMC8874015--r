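#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

state_network_edges <- function(net) {
  g <- net$graph
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- network_ids(net)
  out <- tibble::tibble(from = ids[el[, 1L]], to = ids[el[, 2L]])
  if ("weight" %in% igraph::edge_attr_names(g)) {
    out$weight <- igraph::E(g)$weight
  }
  out
}

#' Tidy a state network into its edge list
#'
#' Broom-style accessors: `tidy()` returns one row per edge, `glance()` the
#' one-row scalar summary from [summarize_network()].
#'
#' @param x a `recurrence_network`, `visibility_network`, or `opn`.
#' @param ... unused.
#' @return `tidy()`: tibble of edges (`from`, `to`, and `weight` where the
#'   network is weighted; OPNs also carry `count` and `probability`).
#'   `glance()`: one-row tibble of network descriptors.
#' @name tidy.state_network
NULL

#' @rdname tidy.state_network
#' @method tidy recurrence_network
#' @export
tidy.recurrence_network <- function(x, ...) state_network_edges(x)

#' @rdname tidy.state_network
#' @method tidy visibility_network
#' @export
tidy.visibility_network <- function(x, ...) state_network_edges(x)

#' @rdname tidy.state_network
#' @method tidy opn
#' @export
tidy.opn <- function(x, ...) {
  nz <- which(x$counts > 0, arr.ind = TRUE)
  ord <- order(nz[, 1L], nz[, 2L])
  nz <- nz[ord, , drop = FALSE]
  tibble::tibble(from = x$patterns[nz[, 1L]],
                 to = x$patterns[nz[, 2L]],
                 count = x$counts[nz],
                 probability = x$probs[nz])
}

#' @rdname tidy.state_network
#' @method glance recurrence_network
#' @export
glance.recurrence_network <- function(x, ...) summarize_network(x)

#' @rdname tidy.state_network
#' @method glance visibility_network
#' @export
glance.visibility_network <- function(x, ...) summarize_network(x)

#' @rdname tidy.state_network
#' @method glance opn
#' @export
glance.opn <- function(x, ...) summarize_network(x)

network_layout_tbl <- function(net, seed = 42L) {
  g <- net$graph
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  ids <- network_ids(net)
  nodes <- tibble::tibble(node = ids, x = xy[, 1L], y = xy[, 2L])
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble::tibble(
    x = xy[el[, 1L], 1L], y = xy[el[, 1L], 2L],
    xend = xy[el[, 2L], 1L], yend = xy[el[, 2L], 2L])
  list(nodes = nodes, edges = edges)
}

plot_state_network <- function(net, title) {
  lay <- network_layout_tbl(net)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = lay$edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      linewidth = 0.3, alpha = 0.5, colour = "grey40") +
    ggplot2::geom_point(
      data = lay$nodes,
      ggplot2::aes(x = .data$x, y = .data$y),
      size = 1.6, colour = "#2c7fb8") +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot methods for state networks
#'
#' `autoplot()` draws the network with a force-directed layout (fixed
#' internal seed, so plots are reproducible). [plot_degree_distribution()]
#' shows the degree histogram, the summary most diagnostic of the dynamical
#' regime (e.g. the exponential tail of a horizontal visibility graph on
#' noise).
#'
#' @param object,net a `state_network`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot recurrence_network
#' @export
autoplot.recurrence_network <- function(object, ...) {
  plot_state_network(
    object,
    sprintf("Recurrence network (epsilon = %.3g, %s)", object$epsilon,
            object$metric))
}

#' @rdname autoplot.recurrence_network
#' @method autoplot visibility_network
#' @export
autoplot.visibility_network <- function(object, ...) {
  plot_state_network(object,
                     paste0(object$variant, " visibility network"))
}

#' @rdname autoplot.recurrence_network
#' @method autoplot opn
#' @export
autoplot.opn <- function(object, ...) {
  plot_state_network(object, "Ordinal partition network")
}

#' @rdname autoplot.recurrence_network
#' @export
plot_degree_distribution <- function(net) {
  g <- if (inherits(net, "state_network")) net$graph else net
  df <- tibble::tibble(degree = igraph::degree(g, mode = "all"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_bar(fill = "#2c7fb8") +
    ggplot2::labs(x = "degree", y = "count",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.recurrence_network
#' @export
plot_epsilon_sweep <- function(net) {
  # `net` here is the tibble from epsilon_sweep()
  df <- tidyr::pivot_longer(net, -"epsilon", names_to = "measure",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epsilon, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "Recurrence threshold sweep")
}
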