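test_that("TSV reading simplifies the graph and normalises pair order", {
  p <- write_lines_tmp(c("A\tB", "B\tC", "C\tA"))
  g <- read_network(p)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)

  p2 <- write_lines_tmp(c("A\tB", "B\tA", "A\tA"))
  expect_message(g2 <- read_network(p2), "self-loop")
  expect_equal(igraph::vcount(g2), 2)
  expect_equal(igraph::ecount(g2), 1)
})

test_that("SIF rows expand to a star from the first node", {
  p <- write_lines_tmp(c("A pp B C", "D pp A"), ext = ".sif")
  g <- read_network(p, format = "sif")
  el <- igraph::as_edgelist(g)
  edges <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  expect_equal(edges, c("A B", "A C", "A D"))
})

test_that("malformed rows are rejected with their line number", {
  p <- write_lines_tmp(c("A\tB", "A\tB\tC"))
  expect_error(read_network(p), "line 2")
  p_sif <- write_lines_tmp(c("A pp B", "A pp"), ext = ".sif")
  expect_error(read_network(p_sif, format = "sif"), "line 2")
  empty <- write_lines_tmp(character(0))
  expect_error(read_network(empty), "empty")
})

test_that("reading is insensitive to row order and round-trips through the writer", {
  rows <- c("A\tB", "B\tC", "C\tD", "D\tA", "B\tD")
  g1 <- read_network(write_lines_tmp(rows))
  g2 <- read_network(write_lines_tmp(rev(rows)))
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    list(nodes = sort(igraph::V(g)$name),
         edges = sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))))
  }
  expect_identical(canon(g1), canon(g2))

  out <- tempfile(fileext = ".tsv")
  write_network(g1, out)
  expect_identical(canon(read_network(out)), canon(g1))
  expect_true(file.exists(paste0(out, ".provenance.json")))
})

test_that("signed-edge reading maps sign tokens and flags unknown ones", {
  p <- write_lines_tmp(c("EZH2\tTP53\trepress", "KLF4\tmiR-429\tactivate",
                         "A\tB\t+1", "C\tD\t-"))
  e <- read_signed_edges(p, layer = "tf_gene")
  expect_equal(e$sign, c(-1L, 1L, 1L, -1L))
  expect_equal(e$layer, rep("tf_gene", 4))

  bad <- write_lines_tmp(c("A\tB\tactivate", "X\tY\tmaybe"))
  expect_error(read_signed_edges(bad, layer = "tf_mirna"), "line 2")
  expect_error(read_signed_edges(p, layer = "nonsense"))
})

test_that("GMT reading collapses duplicate members and enforces unique terms", {
  p <- write_lines_tmp(c("T1\td\tA\tB\tC", "T2\td\tA\tA\tB"), ext = ".gmt")
  sets <- read_gene_sets(p)
  expect_equal(lengths(sets), c(T1 = 3L, T2 = 2L))

  dup <- write_lines_tmp(c("T1\td\tA", "T1\td\tB"), ext = ".gmt")
  expect_error(read_gene_sets(dup), "duplicate term id")
  short <- write_lines_tmp("T1\tonly-description", ext = ".gmt")
  expect_error(read_gene_sets(short), "line 1")
})

test_that("identifier normalisation upper-cases genes and canonicalises miRNAs", {
  expect_equal(normalize_ids(c("tp53", " akt1 ")), c("TP53", "AKT1"))
  expect_equal(normalize_ids(c("HSA-MIR-429", "Mir-133b", "hsa-let-7a")),
               c("hsa-miR-429", "hsa-miR-133b", "hsa-let-7a"))
})
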