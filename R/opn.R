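#' Build an ordinal partition network
#'
#' Maps a symbolic (rank-word) sequence to a directed, weighted
#' state-transition network: one node per distinct ordinal pattern, one edge
#' per observed consecutive pattern pair (self-loops included), with edge
#' weights the empirical conditional probabilities
#' \eqn{p_{ij} = P(S_{t+1} = j \mid S_t = i)}. The terminal symbol
#' contributes a node and a visit but no outgoing transition; rows are
#' normalized over observed outgoing counts only.
#'
#' @param symbols a `tsn_symbols` tibble from [permutation_embed()], or a
#'   character vector of pattern labels.
#' @return object of class `opn` (and `state_network`) with components
#'   `patterns` (labels, order of first appearance), `counts` (transition
#'   count matrix), `probs` (row-normalized; rows with no outgoing
#'   transitions are zero), `visits` (node visit counts), `params`
#'   (`dim`, `lag`, when known), and `graph` (directed weighted igraph).
#' @examples
#' s <- permutation_embed(c(0.1, 0.3, 1.2, 0.2, 0.8, 1.7, 1.3, 0.4, 0.2),
#'                        dim = 3, lag = 2)
#' build_opn(s)
#' @export
build_opn <- function(symbols) {
  labs <- symbol_labels(symbols)
  if (length(labs) < 2L) stop("need at least 2 symbols", call. = FALSE)
  patterns <- unique(labs)
  k <- length(patterns)
  idx <- match(labs, patterns)
  counts <- matrix(0, k, k, dimnames = list(patterns, patterns))
  trans <- cbind(idx[-length(idx)], idx[-1L])
  for (r in seq_len(nrow(trans))) {
    counts[trans[r, 1L], trans[r, 2L]] <- counts[trans[r, 1L], trans[r, 2L]] + 1
  }
  new_opn(counts,
          visits = tabulate(idx, nbins = k),
          params = list(dim = attr(symbols, "dim_embed"),
                        lag = attr(symbols, "lag")))
}

#' @rdname build_opn
#' @export
opn <- build_opn

new_opn <- function(counts, visits = NULL, params = list()) {
  patterns <- rownames(counts)
  out_tot <- rowSums(counts)
  probs <- counts
  nz <- out_tot > 0
  probs[nz, ] <- counts[nz, , drop = FALSE] / out_tot[nz]
  g <- igraph::graph_from_adjacency_matrix(probs, mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  igraph::V(g)$visits <- visits %||% as.integer(out_tot)
  structure(list(patterns = patterns, counts = counts, probs = probs,
                 visits = visits %||% as.integer(out_tot),
                 params = params, graph = g),
            class = c("opn", "state_network"))
}

#' @export
print.opn <- function(x, ...) {
  cat("<ordinal partition network> ", length(x$patterns), " patterns, ",
      sum(x$counts > 0), " transitions (", sum(x$counts),
      " observed steps)", sep = "")
  if (!is.null(x$params$dim)) {
    cat("; d = ", x$params$dim, ", tau = ", x$params$lag, sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Select an embedding dimension for ordinal partition networks
#'
#' Three criteria over a candidate range of dimensions, given a fixed lag:
#' `"degree-variance"` picks the d whose OPN maximizes the variance of the
#' total degree distribution (the richest structure between the saturated
#' complete-ish graph at small d and the path graph at large d);
#' `"pe-first-peak"` picks the first local maximum of permutation entropy
#' across d; `"min-unsaturated"` picks the smallest d whose OPN realizes
#' fewer than d! patterns (the embedding is no longer saturated). Ties go
#' to the smallest d.
#'
#' @inheritParams delay_embed
#' @param lag fixed embedding delay.
#' @param d_range candidate dimensions (default 3:8).
#' @param criterion `"degree-variance"`, `"pe-first-peak"` or
#'   `"min-unsaturated"`.
#' @return integer dimension.
#' @export
select_dimension <- function(x, lag,
                             d_range = 3:8,
                             criterion = c("degree-variance",
                                           "pe-first-peak",
                                           "min-unsaturated"),
                             channel = NULL) {
  criterion <- match.arg(criterion)
  v <- ts_values(x, channel)
  tau <- check_count(lag, "lag", min = 1L)
  d_range <- sort(unique(as.integer(d_range)))
  feasible <- d_range[(d_range - 1L) * tau < length(v) & d_range >= 2L]
  if (length(feasible) == 0L) {
    stop("no feasible dimension in `d_range` for this series length",
         call. = FALSE)
  }
  if (criterion == "min-unsaturated") {
    for (d in feasible) {
      s <- permutation_embed(v, dim = d, lag = tau)
      if (length(unique(s$pattern)) < factorial(d)) return(d)
    }
    stop("all candidate dimensions are saturated; extend `d_range`",
         call. = FALSE)
  }
  score <- vapply(feasible, function(d) {
    s <- permutation_embed(v, dim = d, lag = tau)
    if (criterion == "degree-variance") {
      net <- build_opn(s)
      deg <- igraph::degree(net$graph, mode = "all")
      if (length(deg) > 1L) stats::var(deg) else 0
    } else {
      permutation_entropy(s)
    }
  }, numeric(1))
  if (criterion == "pe-first-peak") {
    peaks <- which(diff(sign(diff(c(-Inf, score, -Inf)))) == -2)
    peaks <- peaks[peaks < length(feasible) | length(feasible) == 1L]
    if (length(peaks) > 0L) return(feasible[peaks[1L]])
    return(feasible[length(feasible)])
  }
  feasible[which.max(score)] # which.max takes the first (smallest d) on ties
}

#' @rdname select_dimension
#' @export
optimal_dim <- select_dimension

#' Permutation entropy
#'
#' Shannon entropy of the empirical ordinal-pattern frequencies — the
#' classical complexity measure of Bandt and Pompe. Maximum is log(d!) when
#' all patterns are equally frequent.
#'
#' @inheritParams build_opn
#' @param base `"e"` (nats, default) or `"2"` (bits).
#' @return non-negative entropy.
#' @export
permutation_entropy <- function(symbols, base = c("e", "2")) {
  base <- match.arg(as.character(base), c("e", "2"))
  labs <- symbol_labels(symbols)
  if (length(labs) == 0L) stop("empty symbol sequence", call. = FALSE)
  p <- table(labs) / length(labs)
  h <- -sum(p * log(p))
  if (base == "2") h <- h / log(2) else h
}

#' Determinism and degeneracy of a state-transition network
#'
#' Effective-information style decomposition of the transition structure.
#' With N nodes and \eqn{W_i} the outgoing distribution of node i (nodes
#' without outgoing transitions are excluded from the average):
#' determinism \eqn{= (\log_2 N - \langle H_2(W_i)\rangle)/\log_2 N}
#' measures how reliably the next state follows from the current one;
#' degeneracy \eqn{= (\log_2 N - H_2(\langle W\rangle))/\log_2 N} measures
#' how much distinct pasts converge on common futures.
#'
#' @param net an `opn` (or any square row-substochastic `probs` object of
#'   the same shape).
#' @return one-row tibble with columns `determinism` and `degeneracy`,
#'   both in `[0, 1]`.
#' @export
determinism_degeneracy <- function(net) {
  P <- net$probs
  N <- nrow(P)
  if (N < 2L) stop("determinism/degeneracy undefined for a single node",
                   call. = FALSE)
  active <- rowSums(P) > 0
  if (!any(active)) stop("no outgoing transitions", call. = FALSE)
  h2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  det <- (log2(N) - mean(apply(P[active, , drop = FALSE], 1L, h2))) / log2(N)
  wbar <- colMeans(P[active, , drop = FALSE])
  deg <- (log2(N) - h2(wbar)) / log2(N)
  tibble::tibble(determinism = det, degeneracy = deg)
}

#' Transition asymmetry per node pair
#'
#' Ordinal partition networks need not be transition-symmetric
#' (\eqn{p_{ij} \ne p_{ji}}). For every unordered pair with
#' \eqn{p_{ij} + p_{ji} > 0} this reports
#' \eqn{|p_{ij} - p_{ji}| / (p_{ij} + p_{ji})}: 0 for balanced pairs, 1 for
#' strictly one-way transitions.
#'
#' @param net an `opn`.
#' @return tibble with columns `from`, `to` (pattern labels, from < to in
#'   node order), `p_ij`, `p_ji`, `asymmetry`.
#' @export
edge_asymmetry <- function(net) {
  P <- net$probs
  k <- nrow(P)
  pairs <- which(upper.tri(P), arr.ind = TRUE)
  pij <- P[pairs]
  pji <- P[pairs[, c(2L, 1L), drop = FALSE]]
  keep <- (pij + pji) > 0
  tibble::tibble(
    from = net$patterns[pairs[keep, 1L]],
    to = net$patterns[pairs[keep, 2L]],
    p_ij = pij[keep], p_ji = pji[keep],
    asymmetry = abs(pij[keep] - pji[keep]) / (pij[keep] + pji[keep]))
}

#' Entropy production of a state-transition network
#'
#' \eqn{\sum_{i,j} p_{ij} \log(p_{ij}/p_{ji})} over transitions with
#' \eqn{p_{ij} > 0}: zero under detailed balance, positive for
#' time-irreversible dynamics. If some transition has no observed reverse
#' (\eqn{p_{ij} > 0}, \eqn{p_{ji} = 0}) the plug-in estimate diverges and
#' `Inf` is returned (a strict-irreversibility flag) unless a pseudocount
#' `alpha > 0` is supplied, which smooths all transition counts before
#' normalization.
#'
#' @param net an `opn`.
#' @param pseudocount alpha >= 0 added to every transition count.
#' @return non-negative number, possibly `Inf`.
#' @export
entropy_production <- function(net, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  C <- net$counts
  if (pseudocount > 0) C <- C + pseudocount
  tot <- rowSums(C)
  P <- C
  nz <- tot > 0
  P[nz, ] <- C[nz, , drop = FALSE] / tot[nz]
  fwd <- P > 0
  if (any(fwd & t(P) == 0)) return(Inf)
  sum(P[fwd] * log(P[fwd] / t(P)[fwd]))
}
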