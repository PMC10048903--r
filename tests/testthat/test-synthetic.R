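canon_edges <- function(g) {
  el <- igraph::as_edgelist(g)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}

test_that("generators are seed-deterministic", {
  expect_identical(canon_edges(gen_scale_free(300, 3, seed = 4)),
                   canon_edges(gen_scale_free(300, 3, seed = 4)))
  s1 <- gen_planted_clusters(80, 0.02, c(5, 6), seed = 9)
  s2 <- gen_planted_clusters(80, 0.02, c(5, 6), seed = 9)
  expect_identical(canon_edges(s1$net), canon_edges(s2$net))
  expect_identical(s1$planted, s2$planted)
  r1 <- gen_signed_regnet(6, 6, 6, seed = 13)
  r2 <- gen_signed_regnet(6, 6, 6, seed = 13)
  expect_identical(r1$edges, r2$edges)
})

test_that("generator preconditions are enforced", {
  expect_error(gen_scale_free(5, 5, seed = 1))      # m < n violated
  expect_error(gen_hierarchical(0, 5))
  expect_error(gen_hierarchical(2, 3))              # base >= 4
  expect_error(gen_planted_clusters(10, 0.5, c(3), seed = 1))  # clique >= 4
  expect_error(gen_signed_regnet(2, 2, 2, planted_ffls = "Z9", seed = 1))
})

test_that("scale-free graphs have a heavy-tailed degree distribution", {
  g <- gen_scale_free(1000, 3, seed = 17)
  expect_true(igraph::is_connected(g))
  f <- fit_power_law_ols(degree_distribution_table(g))
  expect_gte(f$slope, -3.5)
  expect_lte(f$slope, -1.5)
})

test_that("hierarchical construction gives closed modules at depth one", {
  g1 <- gen_hierarchical(1, 5)
  expect_equal(igraph::vcount(g1), 5)
  expect_equal(igraph::ecount(g1), 10)
  expect_equal(node_metrics(g1)$clustering, rep(1, 5))
  # depth-3 tree with base 5: 1 + 4 + 8 modules of 5 nodes
  g3 <- gen_hierarchical(3, 5)
  expect_equal(igraph::vcount(g3), 65)
})

test_that("planted clusters with attach_prob 0 are separate components", {
  sim <- gen_planted_clusters(30, 0, c(5, 4), attach_prob = 0, seed = 6)
  comp <- igraph::components(sim$net)
  for (p in sim$planted) {
    ids <- comp$membership[p]
    expect_equal(length(unique(ids)), 1)
    expect_equal(comp$csize[ids[1]], length(p))
  }
})

test_that("signed generator honours sign constraints", {
  sim <- gen_signed_regnet(10, 10, 10,
                           edge_probs = list(tf_mirna = 0.3, mirna_gene = 0.3,
                                             tf_gene = 0.3),
                           activation_prob = 1, seed = 30)
  e <- sim$edges
  expect_true(all(e$sign[e$layer == "tf_mirna"] == 1L))
  expect_true(all(e$sign[e$layer == "tf_gene"] == 1L))
  expect_true(all(e$sign[e$layer == "mirna_gene"] == -1L))
  # every FFL then has the (+, -, +) incoherent signature
  if (nrow(sim$motifs) > 0) {
    expect_true(all(sim$motifs$type_label == "I1"))
  }
})
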