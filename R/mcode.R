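#' MCODE parameter set
#'
#' Defaults follow the algorithm's canonical settings: vertex weight
#' percentage (node score cutoff) 0.2, haircut on, fluff off with a fluff
#' density cutoff of 0.1, a 2-core post-filter and a maximum expansion depth
#' of 100.
#'
#' @param node_score_cutoff Fraction in `[0, 1)`: a neighbour joins a complex
#'   if its weight is at least `seed_weight * (1 - node_score_cutoff)`.
#' @param haircut Iteratively remove singly-connected members after expansion.
#' @param fluff Add unassigned boundary neighbours whose closed-neighbourhood
#'   density exceeds `fluff_density_cutoff` (applied before haircut).
#' @param fluff_density_cutoff Density threshold for fluff.
#' @param k_core_filter Discard complexes containing no k-core of this order.
#' @param max_depth Maximum breadth-first expansion depth from the seed.
#' @return A list of class `mcode_params`.
#' @export
mcode_params <- function(node_score_cutoff = 0.2, haircut = TRUE,
                         fluff = FALSE, fluff_density_cutoff = 0.1,
                         k_core_filter = 2L, max_depth = 100L) {
  stopifnot(node_score_cutoff >= 0, node_score_cutoff < 1,
            fluff_density_cutoff >= 0, fluff_density_cutoff <= 1,
            k_core_filter >= 0, max_depth >= 1)
  p <- list(node_score_cutoff = node_score_cutoff, haircut = haircut,
            fluff = fluff, fluff_density_cutoff = fluff_density_cutoff,
            k_core_filter = as.integer(k_core_filter),
            max_depth = as.integer(max_depth))
  class(p) <- "mcode_params"
  p
}

.density_simple <- function(n, m) {
  if (n < 2) return(0)
  2 * m / (n * (n - 1))
}

#' MCODE vertex weights (core-clustering coefficient times core order)
#'
#' For each vertex `v`, the closed neighbourhood (v plus its neighbours) is
#' extracted, its highest k-core found, and the weight computed as
#' `k_max * density(highest k-core)` with simple (loop-free) density
#' `2E / (n (n - 1))`. Isolated vertices weigh 0; a vertex whose closed
#' neighbourhood is a single edge gets k_max = 1, density 1, hence weight 1.
#'
#' @param net An undirected simple `igraph` graph.
#' @return Named numeric vector of weights, one per vertex.
#' @export
mcode_vertex_weights <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network", call. = FALSE)
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  w <- numeric(n)
  adj <- igraph::as_adj_list(net)
  for (v in seq_len(n)) {
    nb <- as.integer(adj[[v]])
    if (length(nb) == 0L) next
    sub <- igraph::induced_subgraph(net, c(v, nb))
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_sub <- igraph::induced_subgraph(sub, which(core >= kmax))
    w[[v]] <- kmax * .density_simple(igraph::vcount(core_sub),
                                     igraph::ecount(core_sub))
  }
  names(w) <- nodes
  w
}

#' MCODE cluster score: density times member count
#'
#' `score = 2 * edge_count / (n * (n - 1)) * n`, the ranking criterion for
#' detected complexes. A clique of `n` nodes scores `n`.
#'
#' @param n_members Number of members (>= 2).
#' @param edge_count Edges of the induced subgraph on the members.
#' @return The score, in `(0, n_members]`.
#' @export
#' @examples
#' cluster_score(31, 422)  # 28.13 to two decimals
cluster_score <- function(n_members, edge_count) {
  if (n_members < 2) {
    stop("cluster score needs >= 2 members", call. = FALSE)
  }
  .density_simple(n_members, edge_count) * n_members
}

# iteratively strip degree-1 members: equivalent to taking the 2-core of the
# complex subgraph
.haircut <- function(net, members) {
  repeat {
    sub <- igraph::induced_subgraph(net, members)
    deg <- igraph::degree(sub)
    drop <- igraph::V(sub)$name[deg < 2]
    if (length(drop) == 0L || length(members) <= length(drop)) {
      return(if (length(drop) >= length(members)) character(0)
             else setdiff(members, drop))
    }
    members <- setdiff(members, drop)
  }
}

#' Detect dense complexes with MCODE
#'
#' Seeded-growth molecular complex detection. Vertices are weighted by
#' [mcode_vertex_weights()]; seeds are consumed in weight-descending order
#' (ties by vertex id); from each unassigned seed a breadth-first expansion
#' includes unassigned neighbours whose weight is at least
#' `seed_weight * (1 - node_score_cutoff)`, to at most `max_depth` levels.
#' Each vertex belongs to at most one complex. Post-processing discards
#' complexes with no `k_core_filter`-core, optionally fluffs the boundary,
#' then applies the haircut. Complexes are scored by [cluster_score()] and
#' ranked by score descending (ties: more members first, then smallest id).
#'
#' @param net An undirected simple `igraph` graph.
#' @param params An [mcode_params()] list.
#' @return A `data.frame` of class `mcode_complexes` with columns `rank`,
#'   `score`, `n_nodes`, `n_edges`, `members` (comma-joined ids), plus a
#'   `"member_sets"` attribute holding the member character vectors.
#' @export
mcode <- function(net, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  w <- mcode_vertex_weights(net)
  nodes <- names(w)
  adj <- igraph::as_adj_list(net)
  names(adj) <- nodes
  order_idx <- order(-w, nodes)
  assigned <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  raw <- list()
  for (seed_i in order_idx) {
    seed <- nodes[[seed_i]]
    if (assigned[[seed]] || w[[seed_i]] <= 0) next
    threshold <- w[[seed_i]] * (1 - params$node_score_cutoff)
    members <- seed
    assigned[[seed]] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) > 0L && depth < params$max_depth) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in nodes[as.integer(adj[[v]])]) {
          if (!assigned[[u]] && w[[u]] >= threshold) {
            assigned[[u]] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    if (length(members) > 1L) raw[[length(raw) + 1L]] <- members
  }

  kept <- list()
  for (members in raw) {
    sub <- igraph::induced_subgraph(net, members)
    if (params$k_core_filter > 0 &&
        max(igraph::coreness(sub)) < params$k_core_filter) next
    if (params$fluff) {
      boundary <- unique(unlist(lapply(members, function(v)
        nodes[as.integer(adj[[v]])])))
      boundary <- setdiff(boundary, c(members, nodes[assigned]))
      for (u in boundary) {
        nb <- nodes[as.integer(adj[[match(u, nodes)]])]
        sub_u <- igraph::induced_subgraph(net, c(u, nb))
        if (.density_simple(igraph::vcount(sub_u),
                            igraph::ecount(sub_u)) >
            params$fluff_density_cutoff) {
          members <- c(members, u)
          assigned[[u]] <- TRUE
        }
      }
    }
    if (params$haircut) members <- .haircut(net, members)
    if (length(members) >= 2L) kept[[length(kept) + 1L]] <- sort(members)
  }

  if (length(kept) == 0L) {
    out <- data.frame(rank = integer(0), score = numeric(0),
                      n_nodes = integer(0), n_edges = integer(0),
                      members = character(0), stringsAsFactors = FALSE)
    attr(out, "member_sets") <- list()
    class(out) <- c("mcode_complexes", "data.frame")
    return(out)
  }

  n_nodes <- vapply(kept, length, integer(1))
  n_edges <- as.integer(vapply(kept, function(m)
    igraph::ecount(igraph::induced_subgraph(net, m)), numeric(1)))
  score <- mapply(cluster_score, n_nodes, n_edges)
  first_id <- vapply(kept, `[[`, character(1), 1L)
  ord <- order(-score, -n_nodes, first_id)
  out <- data.frame(rank = seq_along(ord), score = score[ord],
                    n_nodes = n_nodes[ord], n_edges = n_edges[ord],
                    members = vapply(kept[ord], paste, character(1),
                                     collapse = ","),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "member_sets") <- kept[ord]
  class(out) <- c("mcode_complexes", "data.frame")
  out
}

#' Member sets of detected complexes
#'
#' @param complexes An `mcode_complexes` table from [mcode()].
#' @param top Keep only the first `top` complexes (by rank); `Inf` keeps all.
#' @return List of character vectors, one per complex, in rank order.
#' @export
complex_members <- function(complexes, top = Inf) {
  sets <- attr(complexes, "member_sets")
  utils::head(sets, min(length(sets), top))
}
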