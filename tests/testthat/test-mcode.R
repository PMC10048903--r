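clique <- function(ids) {
  pairs <- utils::combn(ids, 2)
  cbind(pairs[1, ], pairs[2, ])
}

test_that("vertex weights follow the core-density rule", {
  k4 <- build_interaction_network(c("a", "a", "a", "b", "b", "c"),
                                  c("b", "c", "d", "c", "d", "d"))
  expect_equal(unname(mcode_vertex_weights(k4)), rep(3, 4))

  star <- build_interaction_network(rep("h", 4), paste0("l", 1:4))
  w <- mcode_vertex_weights(star)
  expect_equal(unname(w["l1"]), 1)  # closed neighbourhood is a single edge

  iso <- build_interaction_network("a", "b", isolated = "z")
  expect_equal(unname(mcode_vertex_weights(iso)["z"]), 0)
})

test_that("cluster score is density times member count", {
  expect_equal(round(cluster_score(31, 422), 2), 28.13)
  expect_equal(cluster_score(7, choose(7, 2)), 7)  # n-clique scores n
  expect_equal(cluster_score(5, 5), 2.5)
  expect_error(cluster_score(1, 0), ">= 2")
  # adding an edge inside a fixed member set strictly increases the score
  expect_true(all(diff(vapply(4:6, cluster_score, numeric(1),
                              n_members = 5)) > 0))
})

test_that("a single clique is recovered whole and trees yield nothing", {
  ids <- paste0("q", 1:6)
  cl <- clique(ids)
  g <- build_interaction_network(cl[, 1], cl[, 2])
  cx <- mcode(g)
  expect_equal(nrow(cx), 1)
  expect_equal(cx$score, 6)
  expect_setequal(complex_members(cx)[[1]], ids)

  tree <- build_interaction_network(rep("r", 5), paste0("t", 1:5))
  expect_equal(nrow(mcode(tree)), 0)
})

test_that("expansion is greedy and seen nodes are consumed exactly once", {
  # two equally dense cliques joined by a direct bridge edge: the expansion
  # crosses the bridge (both cliques clear the weight threshold), so the
  # greedy pass absorbs both into one complex - and no member reappears in a
  # later complex
  c1 <- paste0("a", 1:5)
  c2 <- paste0("b", 1:5)
  ed <- rbind(clique(c1), clique(c2), c("a1", "b1"))
  g <- build_interaction_network(ed[, 1], ed[, 2])
  cx <- mcode(g)
  expect_equal(nrow(cx), 1)
  expect_setequal(complex_members(cx)[[1]], c(c1, c2))

  # the same cliques without the bridge, hanging off a sparse background,
  # are recovered separately
  sim <- gen_planted_clusters(40, 0.02, c(5, 5), attach_prob = 0.05,
                              seed = 3)
  sets <- complex_members(mcode(sim$net), 2)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (p in sim$planted) {
    expect_gte(max(vapply(sets, jac, numeric(1), a = p)), 0.9)
  }
})

test_that("complexes are disjoint, contain a 2-core, and haircut is idempotent", {
  sim <- gen_planted_clusters(120, 0.03, c(7, 5, 5), attach_prob = 0.05,
                              seed = 8)
  cx <- mcode(sim$net)
  sets <- complex_members(cx)
  all_members <- unlist(sets)
  expect_equal(anyDuplicated(all_members), 0)
  for (s in sets) {
    sub <- igraph::induced_subgraph(sim$net, s)
    expect_gte(max(igraph::coreness(sub)), 2)
    # already haircut: no degree-1 members remain (idempotence)
    expect_true(all(igraph::degree(sub) >= 2))
  }
  # ranks sorted by score descending
  expect_true(all(diff(cx$score) <= 0))
  expect_equal(cx$rank, seq_len(nrow(cx)))
})

test_that("planted cliques are recovered with high Jaccard overlap", {
  sim <- gen_planted_clusters(200, 0.01, c(6, 8), attach_prob = 0.02,
                              seed = 11)
  cx <- mcode(sim$net)
  sets <- complex_members(cx, 2)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (p in sim$planted) {
    expect_gte(max(vapply(sets, jac, numeric(1), a = p)), 0.9)
  }
})
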