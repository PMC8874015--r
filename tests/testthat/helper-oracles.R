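# Independent brute-force oracles: direct transcriptions of the defining
# conditions, kept deliberately naive and separate from the implementations
# they check.

# Natural visibility: (i, j) linked iff every intermediate sample lies
# strictly below the chord from (t_i, x_i) to (t_j, x_j).
oracle_nvg_edges <- function(x, t = seq_along(x)) {
  n <- length(x)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ks <- if (j > i + 1L) seq.int(i + 1L, j - 1L) else integer(0)
      chord <- x[j] + (x[i] - x[j]) * (t[j] - t[ks]) / (t[j] - t[i])
      if (all(x[ks] < chord)) { from <- c(from, i); to <- c(to, j) }
    }
  }
  cbind(from, to)
}

# Horizontal visibility: every intermediate strictly below min(x_i, x_j).
oracle_hvg_edges <- function(x) {
  n <- length(x)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ks <- if (j > i + 1L) seq.int(i + 1L, j - 1L) else integer(0)
      if (all(x[ks] < min(x[i], x[j]))) { from <- c(from, i); to <- c(to, j) }
    }
  }
  cbind(from, to)
}

# Recurrence network: strict threshold on the metric, Theiler exclusion.
oracle_rn_edges <- function(pts, epsilon, theiler = 0L,
                            metric = c("euclidean", "chebyshev",
                                       "manhattan")) {
  metric <- match.arg(metric)
  n <- nrow(pts)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- switch(metric,
        euclidean = sqrt(sum((pts[i, ] - pts[j, ])^2)),
        chebyshev = max(abs(pts[i, ] - pts[j, ])),
        manhattan = sum(abs(pts[i, ] - pts[j, ])))
      if (d < epsilon && abs(i - j) > theiler) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  cbind(from, to)
}

# Sample entropy by direct double-loop template counting (Chebyshev);
# both dimensions use the same n - m templates (standard convention).
oracle_sample_entropy <- function(x, m, epsilon) {
  count <- function(mm) {
    n <- length(x) - m
    tot <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)]))
        if (d < epsilon) tot <- tot + 1L
      }
    }
    tot
  }
  A <- count(m + 1L)
  B <- count(m)
  list(sampen = -log(A / B), A = A, B = B)
}

# Shannon entropy (nats) of the empirical distribution of a discrete vector.
oracle_entropy <- function(v) {
  p <- table(v) / length(v)
  -sum(p * log(p))
}

# Canonical string form of an undirected edge set for comparisons.
edge_key <- function(el) {
  if (nrow(el) == 0L) return(character(0))
  a <- pmin(el[, 1L], el[, 2L]); b <- pmax(el[, 1L], el[, 2L])
  sort(paste(a, b, sep = "-"))
}

net_edge_key <- function(net) {
  el <- igraph::as_edgelist(net$graph, names = FALSE)
  edge_key(el)
}

worked_series <- c(0.1, 0.3, 1.2, 0.2, 0.8, 1.7, 1.3, 0.4, 0.2)
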