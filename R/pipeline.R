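#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis in one validated list.
#' All path fields are optional; stages whose inputs are absent are skipped
#' (with a logged reason) rather than failing the whole run.
#'
#' @param network Path to the interaction network (TSV or SIF).
#' @param network_format `"tsv"` or `"sif"`.
#' @param top_n Size of the hub/bottleneck top lists (default 10).
#' @param mcode An [mcode_params()] list.
#' @param retained_complexes Number of top complexes carried into the
#'   crosstalk stage (default 5).
#' @param signed_edges Named list of per-layer signed-edge TSV paths (names
#'   from [regulatory_layers()]).
#' @param target_sources Named list of per-source miRNA-target TSV paths
#'   (columns `mirna`, `gene`).
#' @param min_support Consensus support threshold; `NULL` means all sources.
#' @param gene_sets Path to a GMT file for the enrichment stage.
#' @param ora_threshold Adjusted-p threshold (default 0.05).
#' @param replay_table1,replay_table2 Optional printed-table paths for
#'   [replay_keynodes()] / [replay_crosstalk()] replay mode.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the summary.
#' @param normalize Normalise identifiers on read.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(network = NULL, network_format = "tsv",
                            top_n = 10L, mcode = mcode_params(),
                            retained_complexes = 5L, signed_edges = NULL,
                            target_sources = NULL, min_support = NULL,
                            gene_sets = NULL, ora_threshold = 0.05,
                            replay_table1 = NULL, replay_table2 = NULL,
                            out_dir = tempfile("bnhnet_run_"), seed = 1L,
                            normalize = TRUE) {
  stopifnot(top_n >= 1, retained_complexes >= 1,
            ora_threshold > 0, ora_threshold <= 1)
  for (p in c(network, unlist(signed_edges), unlist(target_sources),
              gene_sets, replay_table1, replay_table2)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured input does not exist: ", p, call. = FALSE)
    }
  }
  cfg <- list(network = network, network_format = network_format,
              top_n = as.integer(top_n), mcode = mcode,
              retained_complexes = as.integer(retained_complexes),
              signed_edges = signed_edges, target_sources = target_sources,
              min_support = min_support, gene_sets = gene_sets,
              ora_threshold = ora_threshold, replay_table1 = replay_table1,
              replay_table2 = replay_table2, out_dir = out_dir,
              seed = as.integer(seed), normalize = normalize)
  class(cfg) <- "pipeline_config"
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the end-to-end network analysis
#'
#' Orchestrates the stages in order: read network -> per-node metrics ->
#' degree aggregation and power-law fits -> key nodes (hubs, bottlenecks,
#' bottleneck-hubs) -> MCODE complexes -> crosstalk matrix and key mediator
#' -> signed regulatory network (consensus targets, assembly, feed-forward
#' and feedback loops) -> over-representation analysis. Stages with missing
#' inputs are skipped and recorded in the summary; a failed stage skips its
#' dependents. All outputs are deterministic functions of the inputs, so a
#' rerun with the same config reproduces every file byte for byte.
#'
#' In replay mode (`replay_table1` / `replay_table2` set), printed hub /
#' bottleneck and crosstalk tables stand in for the network-derived stages,
#' so published worked examples can be reproduced without the source network.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list (also written as `summary.json` in
#'   `out_dir` alongside the per-stage TSVs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = config$seed, stages = list())
  log_stage <- function(name, status, detail = NULL) {
    summary$stages[[name]] <<- c(list(status = status),
                                 if (!is.null(detail)) list(detail = detail))
  }
  out <- function(f) file.path(config$out_dir, f)

  net <- NULL
  metrics <- NULL
  report <- NULL
  complexes <- NULL

  if (!is.null(config$network)) {
    net <- read_network(config$network, config$network_format,
                        normalize = config$normalize)
    summary$network <- list(n_nodes = igraph::vcount(net),
                            n_edges = igraph::ecount(net))
    log_stage("network", "ok")

    metrics <- node_metrics(net)
    .write_tsv(metrics, out("node_metrics.tsv"))
    log_stage("metrics", "ok")

    fits <- fit_all_power_laws(net, metrics)
    summary$fits <- lapply(fits, unclass)
    jsonlite::write_json(summary$fits, out("power_law_fits.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    log_stage("fits", "ok")

    report <- key_node_report(metrics, config$top_n)
    log_stage("keynodes", "ok")

    complexes <- mcode(net, config$mcode)
    .write_tsv(as.data.frame(complexes), out("complexes.tsv"))
    log_stage("mcode", "ok",
              detail = paste(nrow(complexes), "complexes"))
  } else {
    log_stage("network", "skipped", "no network input")
    log_stage("metrics", "skipped", "no network input")
    log_stage("fits", "skipped", "no network input")
  }

  if (!is.null(config$replay_table1)) {
    report <- replay_keynodes(config$replay_table1,
                              normalize = config$normalize)
    log_stage("keynodes", "ok", "replayed from printed table")
  }
  if (!is.null(report)) {
    .write_tsv(report$hubs, out("hubs.tsv"))
    .write_tsv(report$bottlenecks, out("bottlenecks.tsv"))
    jsonlite::write_json(
      list(hubs = report$hubs, bottlenecks = report$bottlenecks,
           bottleneck_hubs = report$bottleneck_hubs),
      out("key_nodes.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
    summary$bottleneck_hubs <- report$bottleneck_hubs
  } else {
    log_stage("keynodes", "skipped", "no network and no replay table")
  }

  xt <- NULL
  if (!is.null(config$replay_table2)) {
    xt <- replay_crosstalk(config$replay_table2,
                           normalize = config$normalize)
    log_stage("crosstalk", "ok", "replayed from printed table")
  } else if (!is.null(net) && !is.null(report) &&
             length(report$bottleneck_hubs) > 0L && nrow(complexes) > 0L) {
    xt <- crosstalk_matrix(net, report$bottleneck_hubs,
                           complex_members(complexes,
                                           config$retained_complexes))
    log_stage("crosstalk", "ok")
  } else {
    log_stage("crosstalk", "skipped",
              "needs a network with bottleneck-hubs and complexes, or a replay table")
  }
  if (!is.null(xt)) {
    .write_tsv(xt, out("crosstalk.tsv"))
    summary$key_mediator <- key_mediator(xt)
    summary$crosstalk_totals <- stats::setNames(as.list(xt$Total), xt$node)
  }

  if (!is.null(config$target_sources)) {
    sources <- lapply(config$target_sources, function(p) {
      tab <- utils::read.delim(p, stringsAsFactors = FALSE)
      if (config$normalize) {
        tab$mirna <- normalize_ids(tab$mirna)
        tab$gene <- normalize_ids(tab$gene)
      }
      tab
    })
    ms <- if (is.null(config$min_support)) length(sources)
          else config$min_support
    consensus <- consensus_targets(sources, ms)
    .write_tsv(consensus, out("consensus_targets.tsv"))
    summary$n_consensus_targets <- nrow(consensus)
    log_stage("consensus", "ok")
  } else {
    log_stage("consensus", "skipped", "no target sources")
  }

  if (!is.null(config$signed_edges)) {
    layer_edges <- mapply(function(p, layer)
      read_signed_edges(p, layer, normalize = config$normalize),
      config$signed_edges, names(config$signed_edges), SIMPLIFY = FALSE)
    regnet <- assemble_regnet(layer_edges)
    ffls <- enumerate_ffls(regnet)
    fbl <- enumerate_feedback_loops(regnet)
    .write_tsv(ffls, out("ffl_motifs.tsv"))
    .write_tsv(fbl, out("feedback_loops.tsv"))
    jsonlite::write_json(regnet$summary, out("regnet_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    summary$regnet <- regnet$summary
    summary$n_ffls <- nrow(ffls)
    summary$n_feedback_loops <- nrow(fbl)
    log_stage("regnet", "ok")
  } else {
    log_stage("regnet", "skipped", "no signed edge inputs")
  }

  if (!is.null(config$gene_sets) && !is.null(report) &&
      length(report$bottleneck_hubs) > 0L) {
    sets <- read_gene_sets(config$gene_sets)
    enr <- tryCatch(
      ora(intersect(report$bottleneck_hubs, unique(unlist(sets))), sets,
          p_threshold = config$ora_threshold),
      error = function(e) NULL)
    if (is.null(enr)) {
      log_stage("enrichment", "skipped",
                "query and annotation universe do not overlap")
    } else {
      .write_tsv(enr, out("enrichment.tsv"))
      summary$n_enriched <- sum(enr$significant)
      log_stage("enrichment", "ok")
    }
  } else {
    log_stage("enrichment", "skipped",
              "needs gene sets and a bottleneck-hub query")
  }

  summary$config <- unclass(config)
  summary$config$mcode <- unclass(config$mcode)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}
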