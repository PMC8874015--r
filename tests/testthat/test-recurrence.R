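test_that("pairwise distances reproduce hand-computed metric values", {
  pts <- rbind(c(0, 0), c(3, 4))
  expect_equal(pairwise_distances(pts, "euclidean")[1, 2], 5)
  expect_equal(pairwise_distances(pts, "manhattan")[1, 2], 7)
  expect_equal(pairwise_distances(pts, "chebyshev")[1, 2], 4)
  # orthogonal unit vectors: cosine distance 1
  orth <- rbind(c(1, 0), c(0, 1))
  expect_equal(pairwise_distances(orth, "cosine")[1, 2], 1)
  # identical points: zero distance everywhere
  same <- rbind(c(1, 2), c(1, 2))
  expect_equal(pairwise_distances(same, "euclidean")[1, 2], 0)
  # correlation distance is 1 - Pearson r
  pr <- rbind(c(1, 2, 3), c(3, 2, 1), c(2, 4, 6))
  dm <- pairwise_distances(pr, "correlation")
  expect_equal(dm[1, 2], 2)
  expect_equal(dm[1, 3], 0)
})

test_that("degenerate vectors are rejected with the offending time index", {
  pts <- rbind(c(1, 1), c(0, 0), c(2, 3))
  expect_error(pairwise_distances(pts, "cosine"), "time index 2")
  expect_error(pairwise_distances(rbind(c(1, 1), c(1, 2)), "correlation"),
               "time index 1")
})

test_that("distance matrices are symmetric, non-negative, zero-diagonal", {
  set.seed(31)
  pts <- matrix(rnorm(60), ncol = 3)
  for (m in c("euclidean", "manhattan", "chebyshev", "cosine",
              "correlation")) {
    dm <- pairwise_distances(pts, m)
    expect_equal(unclass(dm), t(unclass(dm)), ignore_attr = TRUE)
    expect_true(all(dm >= 0))
    expect_equal(unname(diag(dm)), rep(0, nrow(pts)))
  }
})

test_that("recurrence network edges follow the strict threshold rule", {
  # collinear equally spaced points, eps = 1.5: path graph
  pts <- cbind(0:3, 0)
  rn <- build_recurrence_network(pts, epsilon = 1.5)
  expect_equal(net_edge_key(rn), c("1-2", "2-3", "3-4"))
  # eps above max distance: complete graph
  rn_full <- build_recurrence_network(pts, epsilon = 10)
  expect_equal(igraph::ecount(rn_full$graph), choose(4, 2))
  expect_equal(glance(rn_full)$density, 1)
  # eps below min nonzero distance: empty
  rn_empty <- build_recurrence_network(pts, epsilon = 0.5)
  expect_equal(igraph::ecount(rn_empty$graph), 0)
})

test_that("recurrence networks match the brute-force oracle (random clouds)", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(10:60, 1)
    d <- sample(1:3, 1)
    pts <- matrix(rnorm(n * d), ncol = d)
    eps <- runif(1, 0.2, 1.5)
    w <- sample(0:2, 1)
    rn <- build_recurrence_network(pts, epsilon = eps, theiler = w)
    expect_equal(net_edge_key(rn),
                 edge_key(oracle_rn_edges(pts, eps, theiler = w)))
  }
})

test_that("Theiler window suppresses sequential pairs", {
  pts <- cbind(seq(0, 1, length.out = 20), 0)
  rn0 <- build_recurrence_network(pts, epsilon = 0.2, theiler = 0)
  rn2 <- build_recurrence_network(pts, epsilon = 0.2, theiler = 2)
  el <- igraph::as_edgelist(rn2$graph, names = FALSE)
  expect_true(all(abs(el[, 1] - el[, 2]) > 2))
  expect_lt(igraph::ecount(rn2$graph), igraph::ecount(rn0$graph))
})

test_that("weighted recurrence networks carry strictly positive distances", {
  set.seed(43)
  pts <- matrix(rnorm(40), ncol = 2)
  rn <- build_recurrence_network(pts, epsilon = 1.2, weighted = TRUE)
  w <- igraph::E(rn$graph)$weight
  expect_true(all(w > 0))
  expect_true(all(w < 1.2))
})

test_that("edge sets are nested and density non-decreasing in epsilon", {
  set.seed(47)
  pts <- matrix(rnorm(80), ncol = 2)
  grid <- seq(0.1, 3, by = 0.29)
  prev <- character(0)
  prev_density <- 0
  for (eps in grid) {
    rn <- build_recurrence_network(pts, epsilon = eps)
    cur <- net_edge_key(rn)
    expect_true(all(prev %in% cur))
    dens <- igraph::edge_density(rn$graph)
    expect_gte(dens, prev_density)
    prev <- cur; prev_density <- dens
  }
})

test_that("epsilon selection strategies return the stated landmarks", {
  pts <- cbind(c(0, 10, 5), c(0, 0, 0))
  dm <- pairwise_distances(pts)
  expect_equal(select_epsilon(dm, "max-fraction", p = 0.1), 1)
  expect_equal(select_epsilon(dm, "noise-sigma", sigma = 0.2), 1)
  # three equidistant points: any quantile is the common distance
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  dmeq <- pairwise_distances(eq)
  expect_equal(select_epsilon(dmeq, "target-density", rho = 0.5), 1)
  # target-density quantile: half the off-diagonal distances below it
  set.seed(53)
  cl <- matrix(rnorm(60), ncol = 2)
  dmr <- pairwise_distances(cl)
  eps <- select_epsilon(dmr, "target-density", rho = 0.3)
  off <- dmr[upper.tri(dmr)]
  expect_equal(unname(stats::quantile(off, 0.3)), eps)
})

test_that("min-connected epsilon connects the network, and fails loudly", {
  set.seed(59)
  pts <- matrix(rnorm(50), ncol = 2)
  dm <- pairwise_distances(pts)
  eps <- select_epsilon(dm, "min-connected")
  rn <- build_recurrence_network(pts, epsilon = eps)
  expect_equal(igraph::components(rn$graph)$no, 1)
  expect_lte(eps, max(dm))
  expect_error(
    select_epsilon(dm, "min-connected", grid = c(1e-6, 2e-6)),
    "largest component")
})

test_that("max-degree-variance picks the grid argmax", {
  set.seed(61)
  pts <- matrix(rnorm(60), ncol = 2)
  dm <- pairwise_distances(pts)
  grid <- seq(0.3, 3, length.out = 12)
  eps <- select_epsilon(dm, "max-degree-variance", grid = grid)
  dv <- vapply(grid, function(e) {
    stats::var(igraph::degree(
      build_recurrence_network(pts, epsilon = e)$graph))
  }, numeric(1))
  expect_equal(eps, grid[which.max(dv)])
})

test_that("sample entropy equals the direct template-counting oracle", {
  set.seed(67)
  for (rep in 1:8) {
    x <- runif(120)
    eps <- 0.2 * diff(range(x))
    got <- sample_entropy(x, m = 2, epsilon = eps)
    want <- oracle_sample_entropy(x, m = 2, epsilon = eps)
    expect_equal(got$A, want$A)
    expect_equal(got$B, want$B)
    expect_equal(got$sampen, want$sampen)
  }
})

test_that("sample entropy degenerate cases behave as defined", {
  # constant series: every pair recurs at both dimensions, S = -log(1) = 0
  expect_equal(sample_entropy(rep(1, 30), m = 2, epsilon = 0.1)$sampen, 0)
  # widely separated values, tiny epsilon: no recurrences -> explicit error
  expect_error(sample_entropy(1:50, m = 2, epsilon = 1e-6),
               "insufficient recurrences")
})

test_that("state velocity equals per-pair distances", {
  # unit steps along a line
  line <- cbind(0:5, 0)
  v <- state_velocity(line)
  expect_equal(v$velocity, rep(1, 5))
  # repeated identical points
  expect_equal(state_velocity(rbind(c(1, 1), c(1, 1), c(1, 1)))$velocity,
               c(0, 0))
  # random cloud vs direct loop
  set.seed(71)
  pts <- matrix(rnorm(30), ncol = 3)
  got <- state_velocity(pts, "euclidean")$velocity
  want <- vapply(seq_len(nrow(pts) - 1), function(i) {
    sqrt(sum((pts[i, ] - pts[i + 1, ])^2))
  }, numeric(1))
  expect_equal(got, want)
})

test_that("epsilon sweep matches per-threshold network reconstruction", {
  set.seed(73)
  pts <- matrix(rnorm(10), ncol = 2)
  dm <- pairwise_distances(pts)
  grid <- seq(0.2, max(dm) * 1.1, length.out = 8)
  sweep <- epsilon_sweep(dm, grid)
  expect_equal(nrow(sweep), length(grid))
  for (i in seq_along(grid)) {
    g <- build_recurrence_network(pts, epsilon = grid[i])$graph
    expect_equal(sweep$density[i], igraph::edge_density(g))
    expect_equal(sweep$n_components[i], igraph::components(g)$no)
    expect_equal(sweep$degree_variance[i], stats::var(igraph::degree(g)))
  }
  # endpoints: beyond max distance -> complete and connected;
  # density never decreases along the grid
  expect_equal(sweep$density[nrow(sweep)], 1)
  expect_equal(sweep$n_components[nrow(sweep)], 1)
  expect_true(all(diff(sweep$density) >= 0))
  expect_error(epsilon_sweep(dm, c(0.5, 0.4)), "increasing")
})
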