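#' Natural visibility graph of a time series
#'
#' Every sample becomes a node; samples i < j are linked when the straight
#' line between (t_i, x_i) and (t_j, x_j) passes strictly above every
#' intermediate sample. Adjacent samples are always linked (the condition is
#' vacuous), which guarantees the undirected graph is connected. Irregular
#' sampling is supported through explicit `times`. The edge set is invariant
#' under positive affine transformations of the values.
#'
#' Construction sweeps each origin i forward keeping the running maximum
#' slope to intermediates: (i, j) is an edge iff the slope to j strictly
#' exceeds every earlier slope from i. This is O(n^2) overall, against the
#' O(n^3) definition.
#'
#' @inheritParams delay_embed
#' @param times optional strictly increasing sample times (default 1..n; a
#'   `time` column in a data-frame input is used automatically).
#' @param directed orient edges past -> future? Off by default.
#' @return object of class `visibility_network` (and `state_network`)
#'   wrapping an igraph whose vertices carry the sample times.
#' @export
build_natural_visibility <- function(x, times = NULL, directed = FALSE,
                                     channel = NULL) {
  v <- ts_values(x, channel)
  t <- ts_times(x, times, n = length(v))
  el <- nvg_edges(v, t)
  vn_object(el, n = length(v), variant = "natural", directed = directed,
            times = t)
}

nvg_edges <- function(v, t) {
  n <- length(v)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1L)) {
    max_slope <- -Inf
    for (j in seq.int(i + 1L, n)) {
      s <- (v[j] - v[i]) / (t[j] - t[i])
      if (s > max_slope) {
        from <- c(from, i); to <- c(to, j)
      }
      max_slope <- max(max_slope, s)
    }
  }
  cbind(from, to)
}

#' Horizontal visibility graph of a time series
#'
#' The horizontal variant links i < j when every intermediate value is
#' strictly below `min(x_i, x_j)`; adjacent samples are always linked.
#' The horizontal edge set is a subset of the natural visibility edge set on
#' the same input. Built with the standard O(n) monotone-stack scan.
#'
#' @inheritParams build_natural_visibility
#' @return object of class `visibility_network` (and `state_network`).
#' @export
build_horizontal_visibility <- function(x, times = NULL, directed = FALSE,
                                        channel = NULL) {
  v <- ts_values(x, channel)
  t <- ts_times(x, times, n = length(v))
  el <- hvg_edges(v)
  vn_object(el, n = length(v), variant = "horizontal", directed = directed,
            times = t)
}

hvg_edges <- function(v) {
  n <- length(v)
  from <- integer(2L * n); to <- integer(2L * n); m <- 0L
  stack <- integer(n); top <- 0L
  add <- function(i, j) {
    m <<- m + 1L
    if (m > length(from)) { length(from) <<- 2L * m; length(to) <<- 2L * m }
    from[m] <<- i; to[m] <<- j
  }
  for (j in seq_len(n)) {
    while (top > 0L && v[stack[top]] < v[j]) {
      add(stack[top], j)
      top <- top - 1L
    }
    if (top > 0L) {
      add(stack[top], j)
      if (v[stack[top]] == v[j]) top <- top - 1L # equal height blocks further sight
    }
    top <- top + 1L
    stack[top] <- j
  }
  cbind(from = from[seq_len(m)], to = to[seq_len(m)])
}

vn_object <- function(el, n, variant, directed, times) {
  g <- igraph::make_empty_graph(n = n, directed = directed)
  if (nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  igraph::V(g)$time <- times
  igraph::V(g)$name <- as.character(seq_len(n))
  structure(list(graph = g, variant = variant, directed = directed,
                 times = times),
            class = c("visibility_network", "state_network"))
}

#' @export
print.visibility_network <- function(x, ...) {
  cat("<", x$variant, " visibility network> ", igraph::vcount(x$graph),
      " nodes, ", igraph::ecount(x$graph), " edges",
      if (x$directed) " (directed)", "\n", sep = "")
  invisible(x)
}

#' Degree series of a visibility network
#'
#' Symbolizes the original series by replacing every sample with the degree
#' of its node, giving a discrete sequence that preserves temporal order and
#' is amenable to information-theoretic analysis.
#'
#' @param vn a `visibility_network`.
#' @return tibble with columns `time` and `degree` (total degree), one row
#'   per sample.
#' @export
degree_series <- function(vn) {
  stopifnot(inherits(vn, "visibility_network"))
  tibble::tibble(time = vn$times,
                 degree = unname(igraph::degree(vn$graph, mode = "all")))
}

#' Entropy of the degree distribution
#'
#' Shannon entropy (natural log) of the empirical distribution of node
#' degrees — a network-based estimate of the entropy of the underlying
#' signal.
#'
#' @param vn a `visibility_network` (any `state_network` works).
#' @return non-negative entropy in nats.
#' @export
degree_entropy <- function(vn) {
  g <- if (inherits(vn, "state_network")) vn$graph else vn
  p <- table(igraph::degree(g, mode = "all"))
  p <- p / sum(p)
  -sum(p * log(p))
}
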