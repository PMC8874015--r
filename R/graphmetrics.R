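#' Scalar descriptors of a state network
#'
#' One-row summary shared by all network variants: edge density, mean and
#' variance of the degree distribution, global clustering coefficient
#' (transitivity), mean betweenness centrality, number of connected
#' components, and the diameter of the largest component. Recurrence and
#' visibility networks are summarized on their undirected simple graph;
#' ordinal partition networks on the directed weighted graph, with
#' clustering taken on the undirected projection. Betweenness on weighted
#' recurrence networks uses the stored distances as lengths; on OPNs it
#' uses `-log p` so that shortest paths follow most-probable routes.
#'
#' @param net a `state_network` (`recurrence_network`,
#'   `visibility_network`, or `opn`) or a bare igraph.
#' @return one-row tibble: `n_nodes`, `n_edges`, `density`, `mean_degree`,
#'   `degree_variance`, `clustering`, `mean_betweenness`, `n_components`,
#'   `diameter`.
#' @export
summarize_network <- function(net) {
  g <- if (inherits(net, "state_network")) net$graph else net
  if (!igraph::is_igraph(g)) stop("not a network", call. = FALSE)
  if (igraph::vcount(g) == 0L) stop("empty network", call. = FALSE)
  bw_weights <- NULL
  if (inherits(net, "opn")) {
    w <- igraph::E(g)$weight
    bw_weights <- -log(w)
    bw_weights[bw_weights <= 0] <- .Machine$double.eps # p = 1 edges
  } else if (inherits(net, "recurrence_network") && isTRUE(net$weighted)) {
    bw_weights <- igraph::E(g)$weight
  }
  deg <- igraph::degree(g, mode = "all")
  comp <- igraph::components(g, mode = "weak")
  big <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  und <- igraph::as_undirected(g, mode = "collapse")
  tibble::tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    density = igraph::edge_density(g, loops = igraph::any_loop(g)),
    mean_degree = mean(deg),
    degree_variance = if (length(deg) > 1L) stats::var(deg) else 0,
    clustering = igraph::transitivity(und, type = "global"),
    mean_betweenness = mean(igraph::betweenness(g, weights = bw_weights)),
    n_components = comp$no,
    diameter = igraph::diameter(big, weights = NA),
    .rows = 1L)
}

#' Community detection on a state network
#'
#' Finds "macro-states": regions of the state space the system repeatedly
#' returns to (dense subgraphs). Two standard algorithms are exposed,
#' neither endorsed over the other: greedy modularity maximization and the
#' random-walk-based walktrap. Ordinal partition networks are symmetrized
#' first (weight `count_ij + count_ji`); disconnected components are
#' handled independently by both algorithms.
#'
#' @inheritParams summarize_network
#' @param method `"greedy-modularity"` or `"walk-based"`.
#' @param seed integer seed for reproducibility.
#' @return tibble with columns `node` (label) and `community` (contiguous
#'   integers starting at 1).
#' @export
detect_communities <- function(net, method = c("greedy-modularity",
                                               "walk-based"),
                               seed = 1L) {
  method <- match.arg(method)
  seed <- check_count(seed, "seed", min = 0L)
  g <- if (inherits(net, "state_network")) net$graph else net
  if (inherits(net, "opn")) {
    sym <- net$counts + t(net$counts)
    g <- igraph::graph_from_adjacency_matrix(sym, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
  } else if (igraph::is_directed(g)) {
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  g <- igraph::simplify(g, edge.attr.comb = "sum")
  memb <- withr::with_seed(seed, {
    if (igraph::ecount(g) == 0L) {
      seq_len(igraph::vcount(g))
    } else {
      m <- if (method == "greedy-modularity") {
        igraph::membership(igraph::cluster_fast_greedy(g))
      } else {
        igraph::membership(igraph::cluster_walktrap(g))
      }
      # modularity ties (e.g. complete graphs) can split arbitrarily;
      # fall back to the trivial partition unless the split beats it
      w <- igraph::E(g)$weight
      if (igraph::modularity(g, m, weights = w) <=
            igraph::modularity(g, rep(1L, igraph::vcount(g)), weights = w) +
            1e-12) {
        m <- rep(1L, igraph::vcount(g))
      }
      m
    }
  })
  labels <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  tibble::tibble(node = labels,
                 community = as.integer(factor(as.integer(memb))))
}

#' Renormalize an ordinal partition network over macro-states
#'
#' Aggregates micro-state nodes into macro-nodes given a community
#' labeling: macro transition counts are the summed micro counts across the
#' partition (total transition count is conserved) and macro probabilities
#' are re-normalized per macro-node.
#'
#' @param net an `opn`.
#' @param labels node-to-community map: a tibble from
#'   [detect_communities()] (columns `node`, `community`) or a vector of
#'   labels, one per pattern in `net$patterns` order. Every node must be
#'   labeled.
#' @return an `opn` over macro-nodes (labels `"M1"`, `"M2"`, ...).
#' @export
renormalize_opn <- function(net, labels) {
  stopifnot(inherits(net, "opn"))
  k <- length(net$patterns)
  if (is.data.frame(labels)) {
    lab <- labels$community[match(net$patterns, labels$node)]
  } else if (!is.null(names(labels))) {
    lab <- unname(labels[net$patterns])
  } else {
    lab <- labels
  }
  if (length(lab) != k || anyNA(lab)) {
    stop("`labels` must cover every node of the network", call. = FALSE)
  }
  f <- factor(lab)
  agg <- rowsum(t(rowsum(net$counts, f)), f)
  macro <- t(agg)
  dimnames(macro) <- list(paste0("M", seq_len(nlevels(f))),
                          paste0("M", seq_len(nlevels(f))))
  visits <- as.integer(rowsum(matrix(net$visits), f))
  out <- new_opn(macro, visits = visits, params = net$params)
  out
}
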