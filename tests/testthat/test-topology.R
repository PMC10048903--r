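triangle <- build_interaction_network(c("A", "B", "C"), c("B", "C", "A"))
path3 <- build_interaction_network(c("A", "B"), c("B", "C"))
star5 <- build_interaction_network(rep("h", 4), paste0("l", 1:4))

test_that("metrics match hand-computed values on canonical small graphs", {
  m <- node_metrics(triangle)
  expect_equal(m$degree, rep(2L, 3))
  expect_equal(m$clustering, rep(1, 3))
  expect_equal(m$betweenness, rep(0, 3))
  expect_equal(m$closeness, rep(1, 3))
  expect_equal(m$eigenvector, rep(1 / sqrt(3), 3), tolerance = 1e-9)

  mp <- node_metrics(path3)
  b <- mp[mp$node == "B", ]
  expect_equal(b$betweenness, 1)   # only interior node of the only pair
  expect_equal(b$clustering, 0)

  ms <- node_metrics(star5)
  hub <- ms[ms$node == "h", ]
  leaf <- ms[ms$node == "l1", ]
  expect_equal(hub$closeness, 1)
  expect_equal(hub$betweenness, 1)
  expect_equal(leaf$closeness, 4 / 7)
  expect_equal(leaf$neighborhood_connectivity, 4)
  expect_error(node_metrics(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("degree distribution is a probability over observed degrees", {
  expect_equal(degree_distribution_table(triangle), c("2" = 1))
  expect_equal(degree_distribution_table(star5), c("1" = 0.8, "4" = 0.2))
  g <- gen_scale_free(200, 2, seed = 3)
  expect_equal(sum(degree_distribution_table(g)), 1, tolerance = 1e-12)
})

test_that("per-degree aggregation averages within degree classes", {
  ms <- node_metrics(star5)
  expect_equal(aggregate_by_degree(ms, "neighborhood_connectivity"),
               c("1" = 4, "4" = 1))
  expect_equal(aggregate_by_degree(node_metrics(triangle), "clustering"),
               c("2" = 1))
  # one node per degree class: aggregate returns the raw values
  pg <- build_interaction_network(c("a", "b", "c"), c("b", "c", "d"))
  mpg <- node_metrics(pg)
  agg <- aggregate_by_degree(mpg, "closeness")
  expect_equal(unname(agg[as.character(mpg$degree[mpg$node == "a"])][1]),
               mpg$closeness[mpg$node == "a"])
  expect_error(aggregate_by_degree(ms, "pagerank"), "unknown metric")
})

test_that("log-log fit recovers exact and noisy power laws", {
  k <- 1:10
  f <- fit_power_law_ols(stats::setNames(k^(-2), k))
  expect_equal(f$slope, -2, tolerance = 1e-12)
  expect_equal(f$pearson_r, -1, tolerance = 1e-12)

  const <- fit_power_law_ols(stats::setNames(rep(2, 5), 1:5))
  expect_true(const$degenerate)
  expect_equal(const$slope, 0)
  expect_equal(const$pearson_r, 0)

  set.seed(101)
  k20 <- 1:20
  y <- 3 * k20^1.5 * exp(stats::rnorm(20, sd = 0.01))
  fn <- fit_power_law_ols(stats::setNames(y, k20))
  expect_lt(abs(fn$slope - 1.5), 0.1)

  expect_error(fit_power_law_ols(stats::setNames(c(1, 2), 1:2)),
               "insufficient")
})

test_that("centralities agree with brute-force enumeration on small graphs", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    g <- random_connected_graph(n, p = stats::runif(1, 0.3, 0.8))
    m <- node_metrics(g)
    expect_equal(m$betweenness, oracle_betweenness(g), tolerance = 1e-9)
    expect_equal(m$closeness, oracle_closeness(g), tolerance = 1e-9)
    expect_equal(m$eigenvector, oracle_eigenvector(g), tolerance = 1e-9)
  }
})

test_that("betweenness and closeness follow per-component conventions when disconnected", {
  g <- build_interaction_network(c("A", "B", "D"), c("B", "C", "E"))
  m <- node_metrics(g)
  expect_equal(m$betweenness, oracle_betweenness(g), tolerance = 1e-9)
  expect_equal(m$closeness, oracle_closeness(g), tolerance = 1e-9)
  expect_equal(m$closeness[m$node == "D"], 1)
})

test_that("hierarchical graphs show the C(k) decay that rewiring destroys", {
  h <- gen_hierarchical(3, 5)
  f <- fit_power_law_ols(aggregate_by_degree(node_metrics(h), "clustering"))
  expect_lte(f$slope, -0.7)
  sl <- vapply(1:10, function(s) {
    rw <- rewire_preserving_degrees(h, seed = s)
    fit_power_law_ols(aggregate_by_degree(node_metrics(rw),
                                          "clustering"))$slope
  }, numeric(1))
  expect_gt(mean(sl), f$slope + 0.3)  # rewiring flattens the decay
})

test_that("heavy-tailed graphs with a structural cutoff are disassortative", {
  g <- gen_scale_free(2000, 4, seed = 9, exponent = 2)
  f <- fit_power_law_ols(
    aggregate_by_degree(node_metrics(g), "neighborhood_connectivity"))
  expect_lt(f$slope, 0)
})
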