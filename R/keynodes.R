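#' Rank nodes by degree or betweenness
#'
#' Strict top-`n` selection (no expansion of tied tails). Ties are broken by
#' metric descending then node id ascending, so the ranking is deterministic
#' and label-equivariant.
#'
#' @param metrics A [node_metrics()] table, or any data.frame with a `node`
#'   column and the requested metric column.
#' @param by `"degree"` or `"betweenness"`.
#' @param n Number of nodes to keep (default 10, the usual top tier).
#' @return A `data.frame` with columns `node` and `value`, at most `n` rows,
#'   sorted by `value` descending.
#' @export
rank_nodes <- function(metrics, by = c("degree", "betweenness"), n = 10L) {
  by <- match.arg(by)
  stopifnot(n >= 1L)
  ord <- order(-metrics[[by]], metrics$node)
  top <- utils::head(ord, n)
  data.frame(node = metrics$node[top], value = metrics[[by]][top],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bottleneck-hubs: intersection of the hub and bottleneck lists
#'
#' Nodes present in both top lists, ordered by their hub (degree) rank.
#'
#' @param hubs Ranked hub table from [rank_nodes()] (`by = "degree"`).
#' @param bottlenecks Ranked bottleneck table (`by = "betweenness"`).
#' @return Character vector of bottleneck-hub ids in hub-rank order.
#' @export
intersect_key_nodes <- function(hubs, bottlenecks) {
  stopifnot(nrow(hubs) > 0L, nrow(bottlenecks) > 0L)
  hubs$node[hubs$node %in% bottlenecks$node]
}

#' Full key-node report for a network
#'
#' Runs the hub / bottleneck / bottleneck-hub extraction on a metrics table:
#' the top-`n` nodes by degree (hubs), the top-`n` by normalised betweenness
#' (bottlenecks), and their intersection (bottleneck-hubs, the nodes that both
#' concentrate connections and control shortest-path traffic).
#'
#' @param metrics A [node_metrics()] table.
#' @param n Size of each top list (default 10).
#' @return A list of class `key_node_report` with elements `hubs`,
#'   `bottlenecks` (ranked data.frames) and `bottleneck_hubs` (character).
#' @export
key_node_report <- function(metrics, n = 10L) {
  hubs <- rank_nodes(metrics, "degree", n)
  bottlenecks <- rank_nodes(metrics, "betweenness", n)
  out <- list(hubs = hubs, bottlenecks = bottlenecks,
              bottleneck_hubs = intersect_key_nodes(hubs, bottlenecks))
  class(out) <- "key_node_report"
  out
}

#' @exportS3Method base::print
print.key_node_report <- function(x, ...) {
  cat("hubs:        ", paste(x$hubs$node, collapse = ", "), "\n")
  cat("bottlenecks: ", paste(x$bottlenecks$node, collapse = ", "), "\n")
  cat("bottleneck-hubs (", length(x$bottleneck_hubs), "): ",
      paste(x$bottleneck_hubs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Replay key-node extraction from a printed topology table
#'
#' Accepts a table in the layout of a published "top 10 hubs / top 10
#' bottlenecks" listing: columns `hub`, `degree`, `bottleneck`, `betweenness`,
#' one rank per row. Reconstructs the two ranked lists and intersects them,
#' so published worked examples are testable without the underlying network.
#'
#' @param path TSV file with columns `hub`, `degree`, `bottleneck`,
#'   `betweenness`.
#' @param normalize Normalise identifiers via [normalize_ids()].
#' @return A `key_node_report`.
#' @export
replay_keynodes <- function(path, normalize = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("hub", "degree", "bottleneck", "betweenness") %in% names(tab)))
  hub_ids <- if (normalize) normalize_ids(tab$hub) else tab$hub
  bn_ids <- if (normalize) normalize_ids(tab$bottleneck) else tab$bottleneck
  hubs <- data.frame(node = hub_ids, value = tab$degree,
                     stringsAsFactors = FALSE)
  bottlenecks <- data.frame(node = bn_ids, value = tab$betweenness,
                            stringsAsFactors = FALSE)
  hubs <- hubs[order(-hubs$value, hubs$node), , drop = FALSE]
  bottlenecks <- bottlenecks[order(-bottlenecks$value, bottlenecks$node), ,
                             drop = FALSE]
  row.names(hubs) <- row.names(bottlenecks) <- NULL
  out <- list(hubs = hubs, bottlenecks = bottlenecks,
              bottleneck_hubs = intersect_key_nodes(hubs, bottlenecks))
  class(out) <- "key_node_report"
  out
}
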