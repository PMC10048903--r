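#' Scale-free network by preferential attachment
#'
#' Barabasi-Albert growth: each new node attaches to `m` existing nodes with
#' probability proportional to degree. Produces a connected graph with a
#' heavy-tailed degree distribution and disassortative-leaning neighbourhood
#' connectivity, the regime the topology stage expects of a real
#' protein-interaction network.
#'
#' With the default `exponent = NULL` the graph is grown by pure preferential
#' attachment, which is heavy-tailed but (as is well known) asymptotically
#' degree-uncorrelated: its neighbourhood connectivity is flat in `k`. To
#' emulate the disassortative mixing real interactome exports show, set
#' `exponent` (e.g. 2): the graph is then drawn from the static fitness
#' scale-free model with `m * n` edges and the simple-graph constraint, whose
#' structural cutoff makes mean neighbour degree decay with `k`.
#'
#' @param n Number of nodes.
#' @param m Edges added per new node (`1 <= m < n`); under the static model,
#'   `m * n` edges are drawn.
#' @param seed Integer seed (mandatory; generation is seed-deterministic).
#' @param exponent Optional degree-distribution exponent for the static
#'   fitness model; `NULL` (default) selects preferential-attachment growth.
#' @return An undirected simple `igraph` graph with nodes `n1...`.
#' @export
gen_scale_free <- function(n, m, seed, exponent = NULL) {
  stopifnot(n >= 2, m >= 1, m < n)
  set.seed(as.integer(seed))
  g <- if (is.null(exponent)) {
    igraph::sample_pa(n, m = m, directed = FALSE)
  } else {
    stopifnot(exponent > 1)
    igraph::sample_fitness_pl(n, m * n, exponent)
  }
  igraph::V(g)$name <- paste0("n", seq_len(n))
  igraph::simplify(g)
}

#' Deterministic hierarchical-modular network
#'
#' A nested clique-tree construction. The building block is a clique of
#' `base` nodes whose first node acts as the module hub. Modules are
#' arranged in a tree of depth `levels`: a module at depth `d` has
#' `2^(levels - d)` child modules, and every node of a child module is wired
#' to its parent module's hub. `levels = 1` is a single clique.
#'
#' Hubs at successively higher levels therefore accumulate degree in
#' geometric steps while their neighbourhoods grow sparser, which yields the
#' hierarchical signature `C(k) ~ k^-1` exactly by construction (low-degree
#' module members sit in closed cliques with `C = 1`; each hub's
#' neighbourhood is a union of cliques). The geometrically decreasing
#' branching keeps the largest hub below the structural cutoff
#' `sqrt(2 * edges)`, so a degree-preserving random rewiring is an
#' informative null: rewiring flattens C(k) rather than merely re-expressing
#' a density constraint of a dominant hub.
#'
#' The construction is deterministic; `seed` is accepted for interface
#' uniformity only.
#'
#' @param levels Tree depth (>= 1).
#' @param base Module (clique) size (>= 4).
#' @param seed Unused (deterministic construction); kept for a uniform
#'   generator signature.
#' @return An undirected simple `igraph` graph with `base` times the number
#'   of modules nodes (65 for `levels = 3, base = 5`; 525 for
#'   `levels = 4, base = 5`).
#' @export
gen_hierarchical <- function(levels, base, seed = 0L) {
  stopifnot(levels >= 1, base >= 4)
  env <- new.env()
  env$edges <- matrix(integer(0), ncol = 2)
  env$n <- 0L
  new_module <- function() {
    ids <- env$n + seq_len(base)
    env$n <- env$n + as.integer(base)
    env$edges <- rbind(env$edges, t(utils::combn(ids, 2)))
    ids
  }
  frontier <- list(new_module())
  for (d in seq_len(levels - 1L)) {
    n_children <- 2^(levels - d)
    nxt <- list()
    for (mod in frontier) {
      hub <- mod[[1]]
      for (j in seq_len(n_children)) {
        child <- new_module()
        env$edges <- rbind(env$edges, cbind(child, hub))
        nxt[[length(nxt) + 1L]] <- child
      }
    }
    frontier <- nxt
  }
  g <- igraph::make_empty_graph(n = env$n, directed = FALSE)
  igraph::V(g)$name <- paste0("h", seq_len(env$n))
  igraph::simplify(igraph::add_edges(g, t(env$edges)))
}

#' Degree-preserving random rewiring
#'
#' Double-edge-swap randomisation keeping every node's degree fixed;
#' the null model against which the hierarchical clustering signature is
#' judged (rewiring destroys the nested modularity, so C(k) flattens).
#'
#' @param net An undirected `igraph` graph.
#' @param seed Integer seed.
#' @param niter Swap attempts (default 20 per edge).
#' @return A rewired simple `igraph` graph with the same degree sequence.
#' @export
rewire_preserving_degrees <- function(net, seed,
                                      niter = 20 * igraph::ecount(net)) {
  set.seed(as.integer(seed))
  igraph::simplify(
    igraph::rewire(net, igraph::keeping_degseq(loops = FALSE,
                                               niter = niter)))
}

#' Sparse background with planted cliques
#'
#' An Erdos-Renyi background `G(n_background, p_background)` plus one clique
#' per entry of `clique_sizes`, each clique node attached to each background
#' node independently with probability `attach_prob`. The planted membership
#' is returned as ground truth for complex-recovery experiments.
#'
#' @param n_background Background node count.
#' @param p_background Background edge probability (sparse, e.g. 0.01).
#' @param clique_sizes Integer vector of planted clique sizes (each >= 4).
#' @param attach_prob Probability of a clique-to-background edge.
#' @param seed Integer seed.
#' @return List with `net` (igraph) and `planted` (list of member vectors;
#'   clique nodes are named `c<i>_<j>`).
#' @export
gen_planted_clusters <- function(n_background, p_background, clique_sizes,
                                 attach_prob = 0.02, seed = 1L) {
  stopifnot(n_background >= 1, p_background >= 0, p_background <= 1,
            all(clique_sizes >= 4), attach_prob >= 0, attach_prob <= 1)
  set.seed(as.integer(seed))
  bg <- igraph::sample_gnp(n_background, p_background)
  bg_names <- paste0("b", seq_len(n_background))
  igraph::V(bg)$name <- bg_names
  from <- to <- character(0)
  el <- igraph::as_edgelist(bg, names = TRUE)
  from <- el[, 1]; to <- el[, 2]
  planted <- list()
  for (i in seq_along(clique_sizes)) {
    sz <- clique_sizes[[i]]
    ids <- paste0("c", i, "_", seq_len(sz))
    planted[[i]] <- ids
    pairs <- utils::combn(ids, 2)
    from <- c(from, pairs[1, ]); to <- c(to, pairs[2, ])
    for (id in ids) {
      hit <- bg_names[stats::runif(n_background) < attach_prob]
      from <- c(from, rep(id, length(hit))); to <- c(to, hit)
    }
  }
  net <- build_interaction_network(from, to, isolated = bg_names)
  list(net = net, planted = planted)
}

#' Brute-force feed-forward-loop scan
#'
#' Cubic enumeration over all (TF, miRNA, gene) triples of a signed
#' regulatory edge table, kept deliberately naive: it is the reference
#' against which the join-based [enumerate_ffls()] is validated, and the
#' ground-truth recomputation for [gen_signed_regnet()].
#'
#' @param edges Signed edge `data.frame` (`source`, `target`, `sign`,
#'   `layer`).
#' @return Motif `data.frame` in the same layout as [enumerate_ffls()].
#' @export
brute_force_ffls <- function(edges) {
  tm <- edges[edges$layer == "tf_mirna", , drop = FALSE]
  mg <- edges[edges$layer == "mirna_gene", , drop = FALSE]
  tg <- edges[edges$layer == "tf_gene", , drop = FALSE]
  tfs <- unique(c(tm$source, tg$source))
  mirnas <- unique(c(tm$target, mg$source))
  genes <- unique(c(mg$target, tg$target))
  rows <- list()
  for (tf in tfs) for (mi in mirnas) for (g in genes) {
    s1 <- tm$sign[tm$source == tf & tm$target == mi]
    s2 <- mg$sign[mg$source == mi & mg$target == g]
    s3 <- tg$sign[tg$source == tf & tg$target == g]
    if (length(s1) == 1L && length(s2) == 1L && length(s3) == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, mirna = mi, gene = g, sign_tf_mirna = s1,
        sign_mirna_gene = s2, sign_tf_gene = s3, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(tf = character(0), mirna = character(0),
                      gene = character(0), sign_tf_mirna = integer(0),
                      sign_mirna_gene = integer(0),
                      sign_tf_gene = integer(0), coherence = character(0),
                      type_label = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  cls <- classify_ffl(out$sign_tf_mirna, out$sign_mirna_gene,
                      out$sign_tf_gene)
  out$coherence <- cls$coherence
  out$type_label <- cls$type_label
  out <- out[order(out$tf, out$mirna, out$gene), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Random signed tripartite regulatory network with planted FFLs
#'
#' Samples each layer's edges independently with the given probabilities,
#' drawing activation with probability `activation_prob` (miRNA->gene edges
#' are forced repressive, the dominant mode of miRNA action, unless
#' `force_mirna_repression = FALSE`). Requested feed-forward-loop types are
#' then planted on dedicated nodes (`ptf<i>`, `pmi<i>`, `pg<i>`), overwriting
#' any colliding background edge. Ground truth is recomputed from the final
#' edge table by [brute_force_ffls()], so it includes planted and incidental
#' motifs alike.
#'
#' @param n_tf,n_mirna,n_gene Layer sizes.
#' @param edge_probs Named list/vector with entries `tf_mirna`, `mirna_gene`,
#'   `tf_gene` (and optionally `gene_mirna`) giving per-pair edge
#'   probabilities.
#' @param activation_prob Probability that a sampled edge activates.
#' @param planted_ffls Character vector of type labels (`C1`..`C4`,
#'   `I1`..`I4`) to plant; one fresh (TF, miRNA, gene) triple each.
#' @param seed Integer seed.
#' @param force_mirna_repression Force all miRNA->gene background edges to
#'   sign -1 (default TRUE).
#' @return List with `net` (a `signed_regnet`), `edges` (the edge table) and
#'   `motifs` (ground-truth motif table).
#' @export
gen_signed_regnet <- function(n_tf, n_mirna, n_gene,
                              edge_probs = list(tf_mirna = 0.1,
                                                mirna_gene = 0.1,
                                                tf_gene = 0.1,
                                                gene_mirna = 0),
                              activation_prob = 0.5,
                              planted_ffls = character(0), seed = 1L,
                              force_mirna_repression = TRUE) {
  stopifnot(n_tf >= 0, n_mirna >= 0, n_gene >= 0,
            all(unlist(edge_probs) >= 0), all(unlist(edge_probs) <= 1),
            activation_prob >= 0, activation_prob <= 1,
            all(planted_ffls %in% .FFL_TYPES$type_label))
  set.seed(as.integer(seed))
  tfs <- if (n_tf > 0) paste0("tf", seq_len(n_tf)) else character(0)
  mis <- if (n_mirna > 0) paste0("mi", seq_len(n_mirna)) else character(0)
  gs <- if (n_gene > 0) paste0("g", seq_len(n_gene)) else character(0)
  sample_layer <- function(src, tgt, p, layer, force_neg = FALSE) {
    if (length(src) == 0L || length(tgt) == 0L || p <= 0) {
      return(data.frame(source = character(0), target = character(0),
                        sign = integer(0), layer = character(0),
                        stringsAsFactors = FALSE))
    }
    grid <- expand.grid(source = src, target = tgt,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < p
    grid <- grid[keep, , drop = FALSE]
    sgn <- ifelse(stats::runif(nrow(grid)) < activation_prob, 1L, -1L)
    if (force_neg) sgn <- rep(-1L, nrow(grid))
    data.frame(source = grid$source, target = grid$target, sign = sgn,
               layer = layer, stringsAsFactors = FALSE)
  }
  p_of <- function(nm) if (!is.null(edge_probs[[nm]])) edge_probs[[nm]] else 0
  edges <- rbind(
    sample_layer(tfs, mis, p_of("tf_mirna"), "tf_mirna"),
    sample_layer(mis, gs, p_of("mirna_gene"), "mirna_gene",
                 force_neg = force_mirna_repression),
    sample_layer(tfs, gs, p_of("tf_gene"), "tf_gene"),
    sample_layer(gs, mis, p_of("gene_mirna"), "gene_mirna"))
  for (i in seq_along(planted_ffls)) {
    signs <- .FFL_TYPES[.FFL_TYPES$type_label == planted_ffls[[i]], ]
    trip <- c(paste0("ptf", i), paste0("pmi", i), paste0("pg", i))
    edges <- rbind(edges, data.frame(
      source = c(trip[1], trip[2], trip[1]),
      target = c(trip[2], trip[3], trip[3]),
      sign = c(signs$sign_tf_mirna, signs$sign_mirna_gene,
               signs$sign_tf_gene),
      layer = c("tf_mirna", "mirna_gene", "tf_gene"),
      stringsAsFactors = FALSE))
  }
  # planted edges overwrite colliding background edges: keep last occurrence
  key <- paste(edges$source, edges$target, edges$layer, sep = "\r")
  edges <- edges[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  row.names(edges) <- NULL
  list(net = assemble_regnet(edges), edges = edges,
       motifs = brute_force_ffls(edges))
}
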