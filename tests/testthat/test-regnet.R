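pairs_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(mirna = m[, 1], gene = m[, 2], stringsAsFactors = FALSE)
}

test_that("consensus keeps pairs supported by enough sources", {
  src <- list(S1 = pairs_df("a", "G"),
              S2 = pairs_df("a", "G"),
              S3 = pairs_df("a", "G", "b", "G"))
  expect_equal(consensus_targets(src, 3)[, c("mirna", "gene")],
               pairs_df("a", "G"))
  expect_equal(nrow(consensus_targets(src, 1)), 2)  # union
  expect_error(consensus_targets(src, 4), "min_support")
})

test_that("consensus equals brute-force set algebra and is monotone", {
  set.seed(21)
  universe <- expand.grid(mirna = paste0("m", 1:20),
                          gene = paste0("g", 1:10),
                          stringsAsFactors = FALSE)
  src <- lapply(1:3, function(i) universe[sample(200, 50), ])
  names(src) <- paste0("S", 1:3)
  got <- consensus_targets(src, 3)
  keyify <- function(d) sort(paste(d$mirna, d$gene))
  brute <- Reduce(intersect, lapply(src, keyify))
  expect_equal(keyify(got), brute)
  n_at <- vapply(1:3, function(ms) nrow(consensus_targets(src, ms)),
                 integer(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("assembly deduplicates, allows TF+gene dual roles, rejects miRNA conflicts", {
  edges <- data.frame(
    source = c("TF1", "TF1", "TF2", "TP53", "mi1", "TF1"),
    target = c("g1", "g1", "mi1", "mi1", "TP53", "mi1"),
    sign = c(1L, 1L, 1L, 1L, -1L, -1L),
    layer = c("tf_gene", "tf_gene", "tf_mirna", "gene_mirna", "mirna_gene",
              "tf_mirna"),
    stringsAsFactors = FALSE)
  net <- assemble_regnet(edges)
  expect_equal(net$summary$n_edges, 5)  # duplicate collapsed
  expect_setequal(net$roles[["TP53"]], c("gene"))
  expect_setequal(net$roles[["mi1"]], "miRNA")

  dual <- rbind(edges, data.frame(source = "TP53", target = "g1", sign = 1L,
                                  layer = "tf_gene"))
  net2 <- assemble_regnet(dual)
  expect_setequal(net2$roles[["TP53"]], c("gene", "TF"))

  conflict <- data.frame(source = c("TF1", "TF2"), target = c("mi1", "TF1"),
                         sign = 1L, layer = c("tf_mirna", "tf_mirna"))
  expect_error(assemble_regnet(conflict), "role conflict")

  dup_sign <- data.frame(source = "TF1", target = c("g1", "g1"),
                         sign = c(1L, -1L), layer = "tf_gene")
  expect_error(assemble_regnet(dup_sign), "conflicting signs")
})

test_that("all eight sign combinations classify into 4 coherent and 4 incoherent types", {
  grid <- expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1))
  cls <- classify_ffl(grid$s1, grid$s2, grid$s3)
  expect_equal(sum(cls$coherence == "coherent"), 4)
  expect_equal(sum(cls$coherence == "incoherent"), 4)
  expect_setequal(cls$type_label, c(paste0("C", 1:4), paste0("I", 1:4)))
  # coherence iff direct sign equals the indirect product
  expect_equal(cls$coherence == "coherent", grid$s3 == grid$s1 * grid$s2)
  # named cases: activation via a repressive miRNA
  expect_equal(classify_ffl(1, -1, -1)$coherence, "coherent")
  expect_equal(classify_ffl(1, -1, 1)$coherence, "incoherent")
  expect_equal(classify_ffl(1, -1, 1)$type_label, "I1")
  expect_error(classify_ffl(0, 1, 1), "signs")
})

test_that("classification is invariant under double sign flips of the indirect path", {
  grid <- expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1))
  once <- classify_ffl(grid$s1, grid$s2, grid$s3)
  twice <- classify_ffl(-(-grid$s1), -(-grid$s2), grid$s3)
  expect_identical(once, twice)
  # flipping both indirect signs preserves the product, hence coherence
  flipped <- classify_ffl(-grid$s1, -grid$s2, grid$s3)
  expect_equal(flipped$coherence, once$coherence)
})

test_that("join-based FFL enumeration matches the cubic brute-force scan", {
  for (s in 1:12) {
    sim <- gen_signed_regnet(8, 8, 8,
                             edge_probs = list(tf_mirna = 0.15,
                                               mirna_gene = 0.15,
                                               tf_gene = 0.15),
                             activation_prob = 0.5, seed = s)
    expect_equal(enumerate_ffls(sim$net), sim$motifs)
  }
  # no tf_gene edges -> no motifs
  sim0 <- gen_signed_regnet(5, 5, 5,
                            edge_probs = list(tf_mirna = 0.5,
                                              mirna_gene = 0.5, tf_gene = 0),
                            seed = 1)
  expect_equal(nrow(enumerate_ffls(sim0$net)), 0)
})

test_that("planted motifs are returned exactly at zero background density", {
  sim <- gen_signed_regnet(0, 0, 0,
                           edge_probs = list(tf_mirna = 0, mirna_gene = 0,
                                             tf_gene = 0),
                           planted_ffls = c("I1", "I1", "I1"), seed = 2)
  ffl <- enumerate_ffls(sim$net)
  expect_equal(nrow(ffl), 3)
  expect_true(all(ffl$coherence == "incoherent"))
  expect_true(all(ffl$type_label == "I1"))
  mixed <- gen_signed_regnet(0, 0, 0,
                             edge_probs = list(),
                             planted_ffls = c("C1", "C2", "I3"), seed = 3)
  expect_setequal(enumerate_ffls(mixed$net)$type_label, c("C1", "C2", "I3"))
})

test_that("feedback loops multiply reciprocal edge signs", {
  edges <- data.frame(
    source = c("TP53", "JUN", "mi429", "mi429"),
    target = c("mi429", "mi429", "TP53", "JUN"),
    sign = c(1L, -1L, -1L, -1L),
    layer = c("gene_mirna", "gene_mirna", "mirna_gene", "mirna_gene"),
    stringsAsFactors = FALSE)
  fb <- enumerate_feedback_loops(assemble_regnet(edges))
  expect_equal(nrow(fb), 2)
  expect_equal(fb$loop_sign[fb$gene == "TP53"], -1L)  # negative feedback
  expect_equal(fb$loop_sign[fb$gene == "JUN"], 1L)    # double repression
  acyclic <- assemble_regnet(edges[3:4, ])
  expect_equal(nrow(enumerate_feedback_loops(acyclic)), 0)
})

test_that("the curated signed layers reproduce the known loop structure", {
  layers <- list(
    read_signed_edges(extdata("crc_tf_gene.tsv"), "tf_gene", normalize = TRUE),
    read_signed_edges(extdata("crc_tf_mirna.tsv"), "tf_mirna", normalize = TRUE),
    read_signed_edges(extdata("crc_mirna_gene.tsv"), "mirna_gene", normalize = TRUE),
    read_signed_edges(extdata("crc_gene_mirna.tsv"), "gene_mirna", normalize = TRUE))
  net <- assemble_regnet(layers)
  ffl <- enumerate_ffls(net)
  # NFKB1 activates miR-429 which represses EGFR, while NFKB1 activates EGFR:
  # the classic incoherent type-1 wiring
  nf <- ffl[ffl$tf == "NFKB1" & ffl$gene == "EGFR", ]
  expect_equal(nf$type_label, "I1")
  fb <- enumerate_feedback_loops(net)
  expect_equal(fb$loop_sign[fb$gene == "TP53" & fb$mirna == "hsa-miR-429"],
               -1L)
  expect_equal(fb$loop_sign[fb$gene == "JUN" & fb$mirna == "hsa-miR-429"],
               1L)
})
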