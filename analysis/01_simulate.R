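#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a scale-free interactome stand-in, a
# hierarchical-modular graph, a planted-cluster benchmark, signed regulatory
# layers and miRNA-target source lists. Everything is written in the same
# plain-text formats the readers consume, so the downstream scripts depend
# only on files, not on this session.

suppressMessages(library(bnhnet))

seed <- 101L
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

# interactome stand-in: heavy-tailed, disassortative (structural-cutoff regime)
ppi <- gen_scale_free(2000, 4, seed = seed, exponent = 2)
write_network(ppi, file.path(data_dir, "ppi.tsv"))
cat(sprintf("PPI stand-in: %d nodes, %d edges\n",
            igraph::vcount(ppi), igraph::ecount(ppi)))

# hierarchical-modular graph for the C(k) diagnostic
hier <- gen_hierarchical(4, 5)
write_network(hier, file.path(data_dir, "hierarchical.tsv"))
cat(sprintf("hierarchical graph: %d nodes, %d edges\n",
            igraph::vcount(hier), igraph::ecount(hier)))

# planted-cluster benchmark for complex detection
sim <- gen_planted_clusters(200, 0.01, c(6, 8, 5), attach_prob = 0.02,
                            seed = seed + 1L)
write_network(sim$net, file.path(data_dir, "planted.tsv"))
jsonlite::write_json(sim$planted, file.path(data_dir, "planted_truth.json"),
                     pretty = TRUE)
cat(sprintf("planted benchmark: %d nodes, cliques of %s\n",
            igraph::vcount(sim$net),
            paste(lengths(sim$planted), collapse = "/")))

# signed tripartite regulatory network with known motif content
reg <- gen_signed_regnet(12, 12, 12,
                         edge_probs = list(tf_mirna = 0.12, mirna_gene = 0.12,
                                           tf_gene = 0.12, gene_mirna = 0.05),
                         activation_prob = 0.6,
                         planted_ffls = c("I1", "I1", "C2"),
                         seed = seed + 2L)
for (layer in regulatory_layers()) {
  e <- reg$edges[reg$edges$layer == layer, ]
  writeLines(paste(e$source, e$target, ifelse(e$sign > 0, "activate",
                                              "repress"), sep = "\t"),
             file.path(data_dir, paste0(layer, ".tsv")))
}
jsonlite::write_json(reg$motifs, file.path(data_dir, "motif_truth.json"),
                     pretty = TRUE)
cat(sprintf("signed regulatory net: %d nodes, %d edges, %d true FFLs\n",
            reg$net$summary$n_nodes, reg$net$summary$n_edges,
            nrow(reg$motifs)))

# three overlapping miRNA-target sources (consensus fixture)
set.seed(seed + 3L)
universe <- expand.grid(mirna = paste0("hsa-miR-", 1:30),
                        gene = paste0("G", 1:40), stringsAsFactors = FALSE)
core <- universe[sample(nrow(universe), 60), ]
for (s in 1:3) {
  extra <- universe[sample(nrow(universe), 80), ]
  src <- unique(rbind(core[sample(60, 50), ], extra))
  utils::write.table(src, file.path(data_dir, paste0("targets_s", s, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

# gene sets over the planted benchmark for the enrichment stage
members <- igraph::V(sim$net)$name
gmt <- c(
  paste(c("PLANTED1", "first planted clique", sim$planted[[1]]),
        collapse = "\t"),
  paste(c("PLANTED2", "second planted clique", sim$planted[[2]]),
        collapse = "\t"),
  paste(c("PLANTED3", "third planted clique", sim$planted[[3]]),
        collapse = "\t"),
  paste(c("BG1", "background slice", head(members, 50)), collapse = "\t"),
  paste(c("BG2", "another background slice", tail(members, 60)),
        collapse = "\t"))
writeLines(gmt, file.path(data_dir, "sets.gmt"))
cat("inputs written under", data_dir, "\n")
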