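#' Pairwise distance matrix of a point cloud
#'
#' Distances between all pairs of state vectors, either delay-embedded
#' (see [delay_embed()]) or native multichannel vectors. Besides the Lp
#' metrics, the cosine and correlation (1 - Pearson r) distances are
#' offered for high-dimensional recordings where Lp metrics lose contrast.
#'
#' @param cloud point cloud (`tsn_cloud` tibble, data frame of coordinates,
#'   or numeric matrix with one state vector per row).
#' @param metric one of `"euclidean"`, `"manhattan"`, `"chebyshev"`,
#'   `"cosine"`, `"correlation"`.
#' @return symmetric numeric matrix of class `tsn_dist` with zero diagonal;
#'   attribute `metric` records the metric.
#' @export
pairwise_distances <- function(cloud,
                               metric = c("euclidean", "manhattan",
                                          "chebyshev", "cosine",
                                          "correlation")) {
  metric <- match.arg(metric)
  pts <- cloud_matrix(cloud)
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  dm <- switch(metric,
    euclidean = as.matrix(stats::dist(pts, method = "euclidean")),
    manhattan = as.matrix(stats::dist(pts, method = "manhattan")),
    chebyshev = as.matrix(stats::dist(pts, method = "maximum")),
    cosine = {
      nrm <- sqrt(rowSums(pts^2))
      bad <- which(nrm == 0)
      if (length(bad) > 0L) {
        stop("cosine distance undefined for zero vector at time index ",
             cloud_times(cloud)[bad[1L]], call. = FALSE)
      }
      s <- tcrossprod(pts / nrm)
      d <- 1 - pmin(pmax(s, -1), 1)
      diag(d) <- 0
      d
    },
    correlation = {
      sds <- apply(pts, 1L, stats::sd)
      bad <- which(sds == 0)
      if (length(bad) > 0L) {
        stop("correlation distance undefined for constant vector at time index ",
             cloud_times(cloud)[bad[1L]], call. = FALSE)
      }
      d <- 1 - stats::cor(t(pts))
      diag(d) <- 0
      d
    })
  dimnames(dm) <- NULL
  dm[dm < 0] <- 0 # numerical fuzz from dist/cor
  structure(dm, metric = metric, class = c("tsn_dist", class(dm)))
}

#' Build an epsilon-recurrence network
#'
#' Two state vectors are linked when their distance is strictly below
#' `epsilon`; the recurrence plot thresholded this way is read as the
#' adjacency matrix of an undirected network. A Theiler window `theiler`
#' suppresses trivially sequential edges: pairs with `|i - j| <= theiler`
#' are never linked. The weighted variant keeps the (strictly positive)
#' distance on every qualifying edge.
#'
#' @inheritParams pairwise_distances
#' @param epsilon recurrence threshold, > 0 (same units as the metric).
#' @param weighted keep distances as edge weights?
#' @param theiler Theiler window w >= 0; edges require `|i - j| > w`.
#' @return object of class `recurrence_network` (and `state_network`)
#'   wrapping an undirected igraph whose vertices carry the original time
#'   indices.
#' @export
build_recurrence_network <- function(cloud, epsilon,
                                     metric = "euclidean",
                                     weighted = FALSE, theiler = 0L) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("`epsilon` must be a single positive number", call. = FALSE)
  }
  w <- check_count(theiler, "theiler", min = 0L)
  dm <- if (inherits(cloud, "tsn_dist")) cloud else pairwise_distances(cloud, metric)
  metric <- attr(dm, "metric") %||% metric
  n <- nrow(dm)
  adj <- dm < epsilon
  if (w >= 0) {
    idx <- abs(row(adj) - col(adj)) <= w
    adj[idx] <- FALSE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  times <- if (inherits(cloud, "tsn_dist")) seq_len(n) else cloud_times(cloud)
  igraph::V(g)$time <- times
  igraph::V(g)$name <- as.character(times)
  if (weighted) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$weight <- dm[cbind(el[, 1L], el[, 2L])]
  }
  structure(list(graph = g, epsilon = epsilon, metric = metric,
                 theiler = w, weighted = weighted, times = times),
            class = c("recurrence_network", "state_network"))
}

#' @export
print.recurrence_network <- function(x, ...) {
  cat("<recurrence network> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges; epsilon = ",
      format(x$epsilon, digits = 4), ", metric = ", x$metric,
      ", theiler = ", x$theiler, "\n", sep = "")
  invisible(x)
}

#' Recurrence-threshold selection heuristics
#'
#' Standard landmarks for the recurrence threshold epsilon:
#' a fixed fraction of the maximum pairwise distance
#' (`"max-fraction"`), a target edge density realised exactly as a quantile
#' of the off-diagonal distances (`"target-density"`), five times an
#' observational noise level (`"noise-sigma"`), the smallest grid value at
#' which the network becomes fully connected (`"min-connected"`), and the
#' grid value maximizing the degree variance (`"max-degree-variance"`).
#'
#' @param dm distance matrix from [pairwise_distances()].
#' @param strategy selection rule, see above.
#' @param p fraction of the maximum distance (`max-fraction`), 0 < p < 1.
#' @param rho target edge density (`target-density`), 0 < rho < 1.
#' @param sigma noise standard deviation (`noise-sigma`), > 0.
#' @param grid increasing candidate thresholds for the grid strategies;
#'   defaults to 50 values spanning the off-diagonal distance range.
#' @return a single epsilon.
#' @export
select_epsilon <- function(dm,
                           strategy = c("max-fraction", "target-density",
                                        "noise-sigma", "min-connected",
                                        "max-degree-variance"),
                           p = 0.1, rho = 0.1, sigma = NULL, grid = NULL) {
  strategy <- match.arg(strategy)
  off <- dm[upper.tri(dm)]
  if (is.null(grid)) {
    grid <- seq(min(off[off > 0], max(off)), max(off), length.out = 50L)
  }
  switch(strategy,
    "max-fraction" = {
      if (p <= 0 || p >= 1) stop("`p` must be in (0, 1)", call. = FALSE)
      p * max(off)
    },
    "target-density" = {
      if (rho <= 0 || rho >= 1) stop("`rho` must be in (0, 1)", call. = FALSE)
      unname(stats::quantile(off, rho))
    },
    "noise-sigma" = {
      if (is.null(sigma) || sigma <= 0) {
        stop("`sigma` must be a positive number", call. = FALSE)
      }
      5 * sigma
    },
    "min-connected" = {
      best <- NA_real_
      largest <- 0L
      for (eps in sort(grid)) {
        comp <- igraph::components(
          rn_graph_at(dm, eps))
        largest <- max(largest, max(comp$csize))
        if (comp$no == 1L) { best <- eps; break }
      }
      if (is.na(best)) {
        stop("no grid value connects the network; largest component had ",
             largest, " of ", nrow(dm), " nodes", call. = FALSE)
      }
      best
    },
    "max-degree-variance" = {
      dv <- vapply(grid, function(eps) {
        stats::var(igraph::degree(rn_graph_at(dm, eps)))
      }, numeric(1))
      grid[which.max(dv)]
    })
}

rn_graph_at <- function(dm, eps) {
  adj <- dm < eps
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Sample entropy via recurrence counts
#'
#' Sample entropy approximates the entropy rate of a signal as
#' \eqn{-\log(A/B)}, where B is the number of recurrences (template matches
#' within `epsilon`, Chebyshev metric, delay 1) at embedding dimension m and
#' A the number at dimension m + 1. In network terms, A and B are the edge
#' counts of the two recurrence networks (Theiler window 0, strict
#' inequality).
#'
#' @inheritParams delay_embed
#' @param m template length (embedding dimension of the denominator network).
#' @param epsilon similarity threshold, > 0.
#' @param metric distance metric; the conventional choice is `"chebyshev"`.
#' @return list with `sampen` (the entropy, `-log(A/B)`), `A` and `B`.
#'   If either count is zero the function stops with an explicit
#'   "insufficient recurrences" error carrying A and B.
#' @export
sample_entropy <- function(x, m, epsilon, metric = "chebyshev",
                           channel = NULL) {
  v <- ts_values(x, channel)
  m <- check_count(m, "m", min = 1L)
  b_cloud <- if (m == 1L) matrix(v, ncol = 1L) else
    cloud_matrix(delay_embed(v, dim = m, lag = 1L))
  a_cloud <- cloud_matrix(delay_embed(v, dim = m + 1L, lag = 1L))
  # equal template counts at both dimensions (drop the trailing length-m
  # template): a constant series then gives A = B and an entropy of exactly
  # 0, and the estimator is the standard one
  b_cloud <- b_cloud[seq_len(nrow(a_cloud)), , drop = FALSE]
  B <- recurrence_count(b_cloud, epsilon, metric)
  A <- recurrence_count(a_cloud, epsilon, metric)
  if (A == 0L || B == 0L) {
    stop("insufficient recurrences for sample entropy (A = ", A,
         ", B = ", B, "); increase epsilon or the series length",
         call. = FALSE)
  }
  list(sampen = -log(A / B), A = A, B = B)
}

recurrence_count <- function(pts, epsilon, metric) {
  dm <- pairwise_distances(pts, metric)
  sum(dm[upper.tri(dm)] < epsilon)
}

#' State-space velocity profile
#'
#' Distance between consecutive state vectors; for regularly sampled data
#' this is proportional to how fast the system moves through state space at
#' each instant.
#'
#' @inheritParams pairwise_distances
#' @return tibble with columns `time` (index of the earlier point) and
#'   `velocity` (>= 0), one row per consecutive pair.
#' @export
state_velocity <- function(cloud, metric = "euclidean") {
  pts <- cloud_matrix(cloud)
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  a <- pts[-n, , drop = FALSE]
  b <- pts[-1L, , drop = FALSE]
  v <- switch(match.arg(metric, c("euclidean", "manhattan", "chebyshev",
                                  "cosine", "correlation")),
    euclidean = sqrt(rowSums((a - b)^2)),
    manhattan = rowSums(abs(a - b)),
    chebyshev = apply(abs(a - b), 1L, max),
    cosine = ,
    correlation = {
      dm <- pairwise_distances(pts, metric)
      dm[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)]
    })
  tibble::tibble(time = cloud_times(cloud)[-n], velocity = unname(v))
}

#' Summaries of recurrence networks across a threshold sweep
#'
#' Rebuilds the recurrence network at each threshold of an increasing grid
#' (the network filtration obtained by growing epsilon) and reports scalar
#' structure per threshold. Edge sets are nested along the grid, so density
#' is non-decreasing.
#'
#' @param dm distance matrix from [pairwise_distances()].
#' @param grid strictly increasing thresholds.
#' @return tibble with one row per epsilon: `epsilon`, `density`,
#'   `n_components`, `degree_variance`, `clustering` (global transitivity;
#'   NA when undefined).
#' @export
epsilon_sweep <- function(dm, grid) {
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  rows <- lapply(grid, function(eps) {
    g <- rn_graph_at(dm, eps)
    tibble::tibble(
      epsilon = eps,
      density = igraph::edge_density(g),
      n_components = igraph::components(g)$no,
      degree_variance = stats::var(igraph::degree(g)),
      clustering = igraph::transitivity(g, type = "global"))
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
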