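worked_opn <- function() {
  build_opn(permutation_embed(worked_series, dim = 3, lag = 2))
}

test_that("the worked-example OPN has the printed transition structure", {
  net <- worked_opn()
  expect_setequal(net$patterns, c("132", "213", "231"))
  e <- tidy(net)
  out132 <- dplyr::filter(e, from == "132")
  expect_setequal(out132$to, c("213", "231"))
  expect_equal(out132$probability, c(0.5, 0.5))
  # 213 carries a self-loop with weight 0.5
  self213 <- dplyr::filter(e, from == "213", to == "213")
  expect_equal(self213$probability, 0.5)
  # terminal symbol 231 is a node with a visit but no outgoing transition
  expect_equal(net$visits[match("231", net$patterns)], 1L)
  expect_equal(sum(net$counts["231", ]), 0)
})

test_that("degenerate symbol sequences give the expected tiny networks", {
  con <- build_opn(rep("123", 10))
  expect_equal(con$patterns, "123")
  expect_equal(con$probs[1, 1], 1)
  alt <- build_opn(rep(c("12", "21"), 10))
  expect_equal(sort(alt$patterns), c("12", "21"))
  expect_equal(alt$probs["12", "21"], 1)
  expect_equal(alt$probs["21", "12"], 1)
  expect_equal(alt$probs["12", "12"], 0)
})

test_that("rows of the transition matrix are stochastic (property)", {
  set.seed(109)
  for (rep in 1:20) {
    x <- rnorm(sample(50:300, 1))
    d <- sample(2:4, 1)
    net <- build_opn(permutation_embed(x, dim = d, lag = sample(1:3, 1)))
    rs <- rowSums(net$probs)
    active <- rowSums(net$counts) > 0
    expect_true(all(abs(rs[active] - 1) < 1e-12))
    expect_true(all(rs[!active] == 0))
    expect_lte(length(net$patterns), factorial(d))
  }
})

test_that("monotone input gives one node; periodic input a short cycle", {
  mono <- build_opn(permutation_embed(sort(rnorm(50)), dim = 3, lag = 1))
  expect_equal(length(mono$patterns), 1L)
  # period-4 repeating motif: OPN is a directed cycle of at most 4 nodes
  s <- permutation_embed(rep(c(1, 3, 2, 4), 50),
                         dim = 3, lag = 1)
  per <- build_opn(s)
  expect_lte(length(per$patterns), 4L)
  outdeg <- rowSums(per$counts > 0)
  expect_true(all(outdeg == 1))
  # one cycle through all nodes
  g <- per$graph
  expect_equal(igraph::components(g, mode = "strong")$no, 1L)
})

test_that("dimension selection criteria behave as defined", {
  set.seed(113)
  x <- rnorm(2000)
  # white noise saturates d = 3 (all 6 patterns appear)
  s3 <- permutation_embed(x, dim = 3, lag = 1)
  expect_equal(length(unique(s3$pattern)), 6L)
  d_min <- select_dimension(x, lag = 1, criterion = "min-unsaturated")
  expect_gt(d_min, 3)
  s_at <- permutation_embed(x, dim = d_min, lag = 1)
  expect_lt(length(unique(s_at$pattern)), factorial(d_min))
  # monotone series: all criteria tie, smallest d wins
  expect_equal(select_dimension(1:100, lag = 1, d_range = 3:6,
                                criterion = "degree-variance"), 3L)
  # sine fixture: degree-variance equals the exhaustive per-d loop
  sine <- generate_signal("sine", n = 300, period = 24)
  got <- select_dimension(sine, lag = 2, d_range = 3:8,
                          criterion = "degree-variance")
  dv <- vapply(3:8, function(d) {
    net <- build_opn(permutation_embed(sine, dim = d, lag = 2))
    stats::var(igraph::degree(net$graph, mode = "all"))
  }, numeric(1))
  expect_equal(got, (3:8)[which.max(dv)])
  expect_error(select_dimension(rnorm(10), lag = 9, d_range = 3:8), "feasible")
})

test_that("permutation entropy matches direct evaluation", {
  s <- permutation_embed(worked_series, dim = 3, lag = 2)
  # frequencies (2/5, 2/5, 1/5)
  expect_equal(permutation_entropy(s),
               -(0.4 * log(0.4) * 2 + 0.2 * log(0.2)))
  expect_equal(permutation_entropy(s, base = "2"),
               -(0.4 * log2(0.4) * 2 + 0.2 * log2(0.2)))
  expect_equal(permutation_entropy(rep("123", 7)), 0)
  # uniform over all d! patterns attains the maximum log(d!)
  perms <- c("123", "132", "213", "231", "312", "321")
  expect_equal(permutation_entropy(rep(perms, 10)), log(6))
})

test_that("determinism/degeneracy reproduce the closed-form corner cases", {
  ring <- matrix(0, 4, 4, dimnames = rep(list(paste0("p", 1:4)), 2))
  ring[cbind(1:4, c(2, 3, 4, 1))] <- 5
  net_ring <- tsnets:::new_opn(ring)
  dd <- determinism_degeneracy(net_ring)
  expect_equal(dd$determinism, 1)
  expect_equal(dd$degeneracy, 0)
  unif <- matrix(1, 3, 3, dimnames = rep(list(paste0("q", 1:3)), 2))
  dd_u <- determinism_degeneracy(tsnets:::new_opn(unif))
  expect_equal(dd_u$determinism, 0)
  expect_equal(dd_u$degeneracy, 0)
  point <- matrix(0, 3, 3, dimnames = rep(list(paste0("r", 1:3)), 2))
  point[, 2] <- 3
  dd_p <- determinism_degeneracy(tsnets:::new_opn(point))
  expect_equal(dd_p$determinism, 1)
  expect_equal(dd_p$degeneracy, 1)
  single <- matrix(2, 1, 1, dimnames = list("s", "s"))
  expect_error(determinism_degeneracy(tsnets:::new_opn(single)), "single")
})

test_that("edge asymmetry matches hand computation", {
  net <- worked_opn()
  asym <- edge_asymmetry(net)
  # 132 <-> 213: 0.5 each way -> 0; 132 -> 231 one-way -> 1;
  # 213 -> 231 and reverse never observed -> excluded
  expect_equal(nrow(asym), 2L)
  bal <- dplyr::filter(asym, from == "132", to == "213")
  expect_equal(bal$asymmetry, 0)
  one <- dplyr::filter(asym, from == "132", to == "231")
  expect_equal(one$asymmetry, 1)
})

test_that("entropy production is zero under detailed balance, Inf one-way", {
  sym <- matrix(c(2, 3, 3, 2), 2, 2, dimnames = rep(list(c("a", "b")), 2))
  expect_equal(entropy_production(tsnets:::new_opn(sym)), 0)
  cyc <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = rep(list(c("a", "b")), 2))
  expect_equal(entropy_production(tsnets:::new_opn(cyc)), 0) # symmetric two-way
  oneway <- matrix(c(1, 0, 3, 1), 2, 2, dimnames = rep(list(c("a", "b")), 2))
  expect_equal(entropy_production(tsnets:::new_opn(oneway)), Inf)
  expect_lt(entropy_production(tsnets:::new_opn(oneway), pseudocount = 0.5),
            Inf)
  # random row-stochastic matrix vs direct double-sum oracle
  set.seed(127)
  C <- matrix(rpois(16, 5) + 1, 4, 4, dimnames = rep(list(paste0("n", 1:4)), 2))
  net <- tsnets:::new_opn(C)
  P <- net$probs
  want <- 0
  for (i in 1:4) for (j in 1:4) {
    if (P[i, j] > 0) want <- want + P[i, j] * log(P[i, j] / P[j, i])
  }
  expect_equal(entropy_production(net), want)
})

test_that("out-degree variance rises from periodic to chaotic logistic maps", {
  per <- generate_signal("logistic", n = 2000, r = 3.5, x0 = 0.3)
  cha <- generate_signal("logistic", n = 2000, r = 4, x0 = 0.3)
  od_var <- function(sig) {
    net <- build_opn(permutation_embed(sig, dim = 3, lag = 1))
    stats::var(rowSums(net$counts > 0))
  }
  expect_gt(od_var(cha), od_var(per))
})
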