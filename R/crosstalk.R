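#' Interaction strength between a bottleneck-hub and a subnetwork
#'
#' The number of distinct subnetwork members adjacent to the node in the
#' full network, excluding the node itself. Adjacency is evaluated in the
#' full network, not the induced subnetwork, so a bottleneck-hub outside a
#' complex can still score; membership alone contributes nothing (a member of
#' a 31-clique scores at most 30).
#'
#' @param net The full undirected `igraph` network.
#' @param bnh A node id present in `net`.
#' @param members Character vector of subnetwork member ids.
#' @return Integer strength.
#' @export
interaction_strength <- function(net, bnh, members) {
  nodes <- igraph::V(net)$name
  if (!bnh %in% nodes) stop("unknown node '", bnh, "'", call. = FALSE)
  nb <- igraph::V(net)$name[
    as.integer(igraph::neighbors(net, bnh))]
  length(intersect(setdiff(unique(nb), bnh), setdiff(members, bnh)))
}

#' Crosstalk matrix of bottleneck-hubs against subnetworks
#'
#' One row per bottleneck-hub, one column per subnetwork (in rank order),
#' each cell an [interaction_strength()], plus a `Total` column. Rows are
#' sorted by total descending (ties by node id).
#'
#' @param net The full undirected `igraph` network.
#' @param bnhs Character vector of bottleneck-hub ids.
#' @param complexes List of member character vectors (e.g.
#'   [complex_members()]).
#' @return A `data.frame` with columns `node`, `SN-1` ... `SN-k`, `Total`.
#' @export
crosstalk_matrix <- function(net, bnhs, complexes) {
  stopifnot(length(bnhs) > 0L, length(complexes) > 0L)
  cells <- sapply(complexes, function(m)
    vapply(bnhs, interaction_strength, integer(1), net = net, members = m))
  cells <- matrix(as.integer(cells), nrow = length(bnhs),
                  dimnames = list(bnhs, paste0("SN-", seq_along(complexes))))
  out <- data.frame(node = bnhs, cells, Total = as.integer(rowSums(cells)),
                    check.names = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$Total, out$node), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' The key mediator: the bottleneck-hub with the highest crosstalk total
#'
#' @param matrix A crosstalk table with `node` and `Total` columns (from
#'   [crosstalk_matrix()] or [replay_crosstalk()]).
#' @return The node id with the maximum row total (ties: smallest id).
#' @export
key_mediator <- function(matrix) {
  stopifnot(nrow(matrix) > 0L)
  ord <- order(-matrix$Total, matrix$node)
  matrix$node[ord[[1]]]
}

#' Replay a printed crosstalk table
#'
#' Reads a published bottleneck-hub x subnetwork strength table (first column
#' node ids, remaining columns per-subnetwork strengths; any printed total
#' column is ignored) and recomputes row totals and ordering, so published
#' worked examples can be checked without the source network.
#'
#' @param path TSV file; first column node ids, remaining integer columns one
#'   per subnetwork. A column named `Total` (any case) is dropped and
#'   recomputed.
#' @param normalize Normalise node ids via [normalize_ids()].
#' @return A crosstalk `data.frame` as from [crosstalk_matrix()].
#' @export
replay_crosstalk <- function(path, normalize = TRUE) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  stopifnot(ncol(tab) >= 2L)
  ids <- sub("\\*$", "", trimws(tab[[1]]))
  if (normalize) ids <- normalize_ids(ids)
  keep <- setdiff(seq_along(tab)[-1],
                  which(tolower(names(tab)) == "total"))
  cells <- as.matrix(tab[, keep, drop = FALSE])
  storage.mode(cells) <- "integer"
  out <- data.frame(node = ids, cells, Total = as.integer(rowSums(cells)),
                    check.names = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$Total, out$node), , drop = FALSE]
  row.names(out) <- NULL
  out
}
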