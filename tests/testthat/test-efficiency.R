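test_that("graph preparation zeroes the diagonal and handles negative weights", {
  m <- matrix(c(1, 0.5, -0.3, 0.5, 1, 0.2, -0.3, 0.2, 1), 3)
  g <- prepare_weighted_graph(m)
  expect_equal(diag(g$adjacency), c(0, 0, 0))
  expect_equal(g$adjacency[1, 3], 0) # negative correlation dropped
  expect_equal(g$adjacency[1, 2], 0.5) # positive weights preserved
  g_abs <- prepare_weighted_graph(m, negative_weights = "absolute")
  expect_equal(g_abs$adjacency[1, 3], 0.3)
  # identity matrix -> empty graph
  expect_equal(max(prepare_weighted_graph(diag(3))$adjacency), 0)
  asym <- m
  asym[1, 2] <- 0.9
  expect_error(prepare_weighted_graph(asym), "symmetric")
})

test_that("sparsity thresholding keeps exactly the strongest edges, nested across levels", {
  a <- withr::with_seed(5, oracle_random_graph(10, 1)) # complete: 45 edges
  g <- prepare_weighted_graph(a + diag(10) - diag(diag(a)))
  t02 <- threshold_by_sparsity(g, 0.2)
  expect_equal(sum(t02$adjacency > 0) / 2, 9) # round(0.2 * 45)
  # surviving weights are the largest ones, values preserved
  kept <- sort(t02$adjacency[upper.tri(t02$adjacency) & t02$adjacency > 0], decreasing = TRUE)
  expect_equal(kept, sort(a[upper.tri(a)], decreasing = TRUE)[1:9])
  # sparsity 1 leaves a complete graph unchanged
  t1 <- threshold_by_sparsity(g, 1)
  expect_equal(t1$adjacency, g$adjacency)
  # nestedness of retained edge sets over increasing sparsity
  prev <- matrix(FALSE, 10, 10)
  for (s in seq(0.1, 0.9, by = 0.2)) {
    cur <- threshold_by_sparsity(g, s)$adjacency > 0
    expect_true(all(cur[prev]))
    prev <- cur
  }
  # requesting more edges than exist keeps everything with a warning
  sparse_m <- diag(4)
  sparse_m[1, 2] <- sparse_m[2, 1] <- 0.5
  gs <- prepare_weighted_graph(sparse_m)
  expect_warning(out <- threshold_by_sparsity(gs, 0.9), "nonzero edges")
  expect_equal(sum(out$adjacency > 0) / 2, 1)
  expect_error(threshold_by_sparsity(g, 0), "sparsity")
})

test_that("weighted shortest paths invert weights and match Floyd-Warshall", {
  # two nodes joined by weight 2 -> distance 1/2
  a <- matrix(c(0, 2, 2, 0), 2)
  g <- structure(list(adjacency = a, node_labels = c("a", "b")), class = "weighted_graph")
  expect_equal(weighted_shortest_paths(g)["a", "b"], 0.5)
  # path a-b-c with unit weights, no direct a-c edge
  p <- matrix(0, 3, 3)
  p[1, 2] <- p[2, 1] <- 1
  p[2, 3] <- p[3, 2] <- 1
  gp <- prepare_weighted_graph(p + diag(3))
  expect_equal(weighted_shortest_paths(gp)[1, 3], 2)
  # disconnected pairs are Inf
  d4 <- prepare_weighted_graph(diag(4))
  expect_true(all(is.infinite(weighted_shortest_paths(d4)[upper.tri(diag(4))])))
  # random 8-node graphs against the Floyd-Warshall oracle
  for (s in 1:25) {
    a <- withr::with_seed(s, oracle_random_graph(8, 0.4))
    g <- prepare_weighted_graph(a + diag(8))
    expect_equal(
      weighted_shortest_paths(g),
      oracle_floyd_warshall(oracle_lengths(a)),
      tolerance = 1e-10, ignore_attr = TRUE
    )
  }
  # and the Floyd-Warshall oracle itself against exhaustive simple-path
  # enumeration on smaller graphs
  for (s in 1:8) {
    a <- withr::with_seed(100 + s, oracle_random_graph(6, 0.5))
    lenm <- oracle_lengths(a)
    expect_equal(
      oracle_floyd_warshall(lenm),
      oracle_enum_all_distances(lenm),
      tolerance = 1e-10
    )
  }
})

test_that("global and local efficiency match hand-evaluated toys", {
  # complete graph with unit weights
  cm <- matrix(1, 6, 6)
  g <- prepare_weighted_graph(cm)
  expect_equal(global_efficiency(g), 1)
  expect_equal(local_efficiency(g), 1)
  # edgeless graph
  g0 <- prepare_weighted_graph(diag(5))
  expect_equal(global_efficiency(g0), 0)
  expect_equal(local_efficiency(g0), 0)
  # 3-node unit path: inverse distances 1, 1, 1/2 over unordered pairs
  p <- matrix(0, 3, 3)
  p[1, 2] <- p[2, 1] <- 1
  p[2, 3] <- p[3, 2] <- 1
  gp <- prepare_weighted_graph(p + diag(3))
  expect_equal(global_efficiency(gp), 5 / 6)
  # star graph: leaves have degree 1, hub's neighbours are mutually
  # unreachable inside the neighbour subgraph
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.8
  gs <- prepare_weighted_graph(star + diag(5))
  expect_equal(local_efficiency(gs), 0)
  expect_error(global_efficiency(prepare_weighted_graph(matrix(1, 1, 1))), "2 nodes")
})

test_that("efficiency is monotone in sparsity and scales as expected", {
  a <- withr::with_seed(9, oracle_random_graph(12, 0.8))
  g <- prepare_weighted_graph(a + diag(12))
  egs <- suppressWarnings(vapply(
    seq(0.1, 1, by = 0.1),
    function(s) global_efficiency(threshold_by_sparsity(g, s)), 0
  ))
  expect_true(all(diff(egs) >= -1e-12)) # adding edges never hurts integration
  # single-edge inverse distance scales linearly with the weight
  two <- matrix(c(0, 0.5, 0.5, 0), 2)
  gt <- structure(list(adjacency = two, node_labels = c("a", "b")), class = "weighted_graph")
  gt3 <- structure(list(adjacency = two * 3, node_labels = c("a", "b")), class = "weighted_graph")
  expect_equal(global_efficiency(gt3), 3 * global_efficiency(gt))
})

test_that("efficiency curves integrate by the trapezoidal rule", {
  # complete unit graph: both metrics are exactly 1 at every sparsity where
  # the retained subgraph stays connected at full weight; use sparsity 1 only
  m <- withr::with_seed(2, random_symmetric_matrix(12))
  curve <- suppressWarnings(efficiency_curve(m))
  expect_length(curve$sparsities, 10) # 5% to 50% in 5% steps
  expect_equal(curve$sparsities, seq(0.05, 0.5, by = 0.05))
  expect_equal(
    curve$eg_auc,
    sum(diff(curve$sparsities) * (head(curve$eg_values, -1) + tail(curve$eg_values, -1)) / 2)
  )
  # a constant metric of value c over width 0.45 integrates to 0.45 c
  cm <- matrix(1, 8, 8)
  expect_equal(
    switchconn:::trapezoid_auc(seq(0.05, 0.5, 0.05), rep(0.7, 10)),
    0.45 * 0.7
  )
  # two-point hand example: trapezoid of (0.1, 0.4) and (0.2, 0.6)
  expect_equal(switchconn:::trapezoid_auc(c(0.1, 0.2), c(0.4, 0.6)), 0.05)
  expect_error(efficiency_curve(cm, sparsities = c(0.5, 0.3)), "increasing")
})

test_that("pooled two-sample t matches hand evaluation and df convention", {
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$t_statistic, -3.674235, tolerance = 1e-6)
  expect_equal(cmp$degrees_of_freedom, 4)
  # two groups of 46 give the df = 90 of the standard cohort comparison
  a <- withr::with_seed(1, rnorm(46))
  b <- withr::with_seed(2, rnorm(46))
  expect_equal(compare_groups(a, b)$degrees_of_freedom, 90)
  # identical groups: t = 0, p = 1
  same <- c(1, 2, 3, 4)
  cmp0 <- compare_groups(same, same)
  expect_equal(cmp0$t_statistic, 0)
  expect_equal(cmp0$p_value, 1)
  expect_error(compare_groups(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
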