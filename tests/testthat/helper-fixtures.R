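# On-the-fly fixture writers for reader and pipeline tests.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

extdata <- function(f) {
  system.file("extdata", f, package = "bnhnet", mustWork = TRUE)
}

# small end-to-end input bundle: a planted-cluster PPI network plus signed
# regulatory layers and a GMT, written to a temp dir
pipeline_fixture <- function(dir = tempfile("fix_"), seed = 42L) {
  dir.create(dir)
  sim <- gen_planted_clusters(60, 0.02, c(6, 5), attach_prob = 0.05,
                              seed = seed)
  net_path <- file.path(dir, "network.tsv")
  write_network(sim$net, net_path)
  layers <- list(
    tf_gene = c("TF1\tG1\trepress", "TF2\tG1\tactivate", "TF1\tG2\tactivate"),
    tf_mirna = c("TF1\thsa-miR-1\tactivate", "TF2\thsa-miR-1\trepress"),
    mirna_gene = c("hsa-miR-1\tG1\trepress", "hsa-miR-1\tG2\trepress"),
    gene_mirna = c("G1\thsa-miR-1\tactivate"))
  layer_paths <- lapply(names(layers), function(l) {
    p <- file.path(dir, paste0(l, ".tsv"))
    writeLines(layers[[l]], p)
    p
  })
  names(layer_paths) <- names(layers)
  src <- list(
    s1 = c("mirna\tgene", "hsa-miR-1\tG1", "hsa-miR-1\tG2", "hsa-miR-2\tG1"),
    s2 = c("mirna\tgene", "hsa-miR-1\tG1", "hsa-miR-2\tG1"),
    s3 = c("mirna\tgene", "hsa-miR-1\tG1", "hsa-miR-1\tG2"))
  src_paths <- lapply(names(src), function(s) {
    p <- file.path(dir, paste0(s, ".tsv"))
    writeLines(src[[s]], p)
    p
  })
  names(src_paths) <- names(src)
  gmt <- file.path(dir, "sets.gmt")
  members <- igraph::V(sim$net)$name
  writeLines(c(
    paste(c("T1", "planted one", sim$planted[[1]]), collapse = "\t"),
    paste(c("T2", "planted two", sim$planted[[2]]), collapse = "\t"),
    paste(c("T3", "background", utils::head(members, 30)), collapse = "\t")),
    gmt)
  list(dir = dir, network = net_path, layers = layer_paths,
       sources = src_paths, gmt = gmt, sim = sim)
}
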