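#' Consensus miRNA-target pairs across prediction sources
#'
#' Keeps the (miRNA, gene) pairs supported by at least `min_support` of the
#' supplied sources. With the default (`min_support = number of sources`)
#' this is the strict intersection used to retain only targets predicted by
#' every database; `min_support = 1` gives the union. Raising `min_support`
#' never adds pairs.
#'
#' @param sources Named list; each element a `data.frame` with columns
#'   `mirna` and `gene` (one prediction source).
#' @param min_support Minimum number of sources a pair must appear in.
#' @return A `data.frame` with columns `mirna`, `gene`, `support`, sorted by
#'   miRNA then gene.
#' @export
consensus_targets <- function(sources, min_support = length(sources)) {
  stopifnot(length(sources) >= 1L)
  if (min_support < 1 || min_support > length(sources)) {
    stop("min_support must be in [1, ", length(sources), "]", call. = FALSE)
  }
  keys <- lapply(sources, function(s)
    unique(paste(trimws(s$mirna), trimws(s$gene), sep = "\r")))
  tab <- table(unlist(keys))
  hit <- names(tab)[tab >= min_support]
  parts <- strsplit(hit, "\r", fixed = TRUE)
  out <- data.frame(
    mirna = vapply(parts, `[[`, character(1), 1L),
    gene = vapply(parts, `[[`, character(1), 2L),
    support = as.integer(tab[hit]),
    stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  row.names(out) <- NULL
  out
}

.LAYER_ROLES <- list(
  tf_gene = c("TF", "gene"),
  tf_mirna = c("TF", "miRNA"),
  mirna_gene = c("miRNA", "gene"),
  gene_mirna = c("gene", "miRNA"))

#' Assemble a signed tripartite regulatory network
#'
#' Combines per-layer signed edge tables (see [read_signed_edges()]) into one
#' directed signed network over TF, miRNA and gene nodes. Duplicate
#' (source, target, layer) triples collapse to one edge (conflicting signs on
#' a duplicate are an error). A node may act as both TF and gene (a hub gene
#' that itself regulates a miRNA); any role combination involving miRNA and a
#' non-miRNA role is rejected.
#'
#' @param edges A `data.frame` of signed edges with columns `source`,
#'   `target`, `sign`, `layer`, or a list of such frames (rbind-ed).
#' @return A list of class `signed_regnet`: `edges` (deduplicated
#'   data.frame), `roles` (named list node -> character vector of roles),
#'   `summary` (node/edge counts per role/layer).
#' @export
assemble_regnet <- function(edges) {
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, edges)
  }
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "sign", "layer") %in% names(edges)))
  if (!all(edges$sign %in% c(-1L, 1L))) {
    stop("signs must be +1 or -1", call. = FALSE)
  }
  if (!all(edges$layer %in% names(.LAYER_ROLES))) {
    stop("unknown layer(s): ",
         paste(setdiff(unique(edges$layer), names(.LAYER_ROLES)),
               collapse = ", "), call. = FALSE)
  }
  key <- paste(edges$source, edges$target, edges$layer, sep = "\r")
  first <- !duplicated(key)
  sign_by_key <- tapply(edges$sign, key, function(s) length(unique(s)))
  if (any(sign_by_key > 1)) {
    stop("conflicting signs for duplicated edge(s)", call. = FALSE)
  }
  edges <- edges[first, , drop = FALSE]
  row.names(edges) <- NULL

  roles <- list()
  add_role <- function(node, role) {
    roles[[node]] <<- union(roles[[node]], role)
  }
  for (i in seq_len(nrow(edges))) {
    rr <- .LAYER_ROLES[[edges$layer[[i]]]]
    add_role(edges$source[[i]], rr[[1]])
    add_role(edges$target[[i]], rr[[2]])
  }
  for (node in names(roles)) {
    r <- roles[[node]]
    if ("miRNA" %in% r && length(r) > 1L) {
      stop("role conflict for node '", node,
           "': miRNA combined with ", paste(setdiff(r, "miRNA"),
                                            collapse = "/"), call. = FALSE)
    }
  }
  role_counts <- table(unlist(roles))
  net <- list(
    edges = edges,
    roles = roles,
    summary = list(
      n_nodes = length(roles),
      n_edges = nrow(edges),
      nodes_per_role = as.list(role_counts),
      edges_per_layer = as.list(table(edges$layer))))
  class(net) <- "signed_regnet"
  net
}

#' @exportS3Method base::print
print.signed_regnet <- function(x, ...) {
  cat("signed regulatory network:", x$summary$n_nodes, "nodes,",
      x$summary$n_edges, "edges\n")
  cat("  per layer:",
      paste(names(x$summary$edges_per_layer),
            unlist(x$summary$edges_per_layer), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

.FFL_TYPES <- data.frame(
  sign_tf_mirna = c(1, -1, 1, -1, 1, -1, 1, -1),
  sign_mirna_gene = c(1, -1, -1, 1, -1, -1, 1, 1),
  sign_tf_gene = c(1, 1, -1, -1, 1, -1, -1, 1),
  type_label = c("C1", "C2", "C3", "C4", "I1", "I2", "I3", "I4"),
  stringsAsFactors = FALSE)

#' Classify a feed-forward loop by its edge signs
#'
#' A TF->miRNA->gene feed-forward loop is *coherent* when the sign of the
#' direct TF->gene edge equals the product of the two indirect signs
#' (TF->miRNA times miRNA->gene), *incoherent* otherwise. The eight sign
#' combinations map to the standard four coherent (C1-C4) and four
#' incoherent (I1-I4) types:
#' C1 (+,+,+), C2 (-,-,+), C3 (+,-,-), C4 (-,+,-),
#' I1 (+,-,+), I2 (-,-,-), I3 (+,+,-), I4 (-,+,+).
#'
#' @param sign_tf_mirna,sign_mirna_gene,sign_tf_gene Signs in `{-1, +1}`
#'   (vectorised).
#' @return A `data.frame` with columns `coherence` (`"coherent"` /
#'   `"incoherent"`) and `type_label`.
#' @export
classify_ffl <- function(sign_tf_mirna, sign_mirna_gene, sign_tf_gene) {
  s <- c(sign_tf_mirna, sign_mirna_gene, sign_tf_gene)
  if (!all(s %in% c(-1, 1))) {
    stop("signs must be +1 or -1", call. = FALSE)
  }
  coherent <- sign_tf_gene == sign_tf_mirna * sign_mirna_gene
  idx <- match(paste(sign_tf_mirna, sign_mirna_gene, sign_tf_gene),
               paste(.FFL_TYPES$sign_tf_mirna, .FFL_TYPES$sign_mirna_gene,
                     .FFL_TYPES$sign_tf_gene))
  data.frame(coherence = ifelse(coherent, "coherent", "incoherent"),
             type_label = .FFL_TYPES$type_label[idx],
             stringsAsFactors = FALSE)
}

#' Enumerate TF-miRNA-gene feed-forward loops
#'
#' Finds every (TF, miRNA, gene) triple for which the network contains all
#' three edges TF->miRNA (`tf_mirna` layer), miRNA->gene (`mirna_gene`) and
#' TF->gene (`tf_gene`), and classifies each with [classify_ffl()].
#' Implemented by joining the three layer tables on shared endpoints, so it
#' scales with the number of realised two-paths rather than all triples.
#'
#' @param net A `signed_regnet` from [assemble_regnet()].
#' @return A `data.frame` with columns `tf`, `mirna`, `gene`, the three
#'   signs, `coherence` and `type_label`, sorted by (tf, mirna, gene).
#' @export
enumerate_ffls <- function(net) {
  stopifnot(inherits(net, "signed_regnet"))
  e <- net$edges
  tm <- e[e$layer == "tf_mirna", c("source", "target", "sign")]
  mg <- e[e$layer == "mirna_gene", c("source", "target", "sign")]
  tg <- e[e$layer == "tf_gene", c("source", "target", "sign")]
  empty <- data.frame(tf = character(0), mirna = character(0),
                      gene = character(0), sign_tf_mirna = integer(0),
                      sign_mirna_gene = integer(0), sign_tf_gene = integer(0),
                      coherence = character(0), type_label = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(tm) == 0L || nrow(mg) == 0L || nrow(tg) == 0L) return(empty)
  names(tm) <- c("tf", "mirna", "sign_tf_mirna")
  names(mg) <- c("mirna", "gene", "sign_mirna_gene")
  names(tg) <- c("tf", "gene", "sign_tf_gene")
  two_path <- merge(tm, mg, by = "mirna")
  if (nrow(two_path) == 0L) return(empty)
  ffl <- merge(two_path, tg, by = c("tf", "gene"))
  if (nrow(ffl) == 0L) return(empty)
  cls <- classify_ffl(ffl$sign_tf_mirna, ffl$sign_mirna_gene,
                      ffl$sign_tf_gene)
  out <- data.frame(tf = ffl$tf, mirna = ffl$mirna, gene = ffl$gene,
                    sign_tf_mirna = ffl$sign_tf_mirna,
                    sign_mirna_gene = ffl$sign_mirna_gene,
                    sign_tf_gene = ffl$sign_tf_gene,
                    coherence = cls$coherence, type_label = cls$type_label,
                    stringsAsFactors = FALSE)
  out <- out[order(out$tf, out$mirna, out$gene), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Enumerate gene-miRNA feedback loops
#'
#' All (gene, miRNA) pairs with reciprocal regulation: a gene->miRNA edge
#' (`gene_mirna` layer, the gene acting as a transcriptional regulator of the
#' miRNA) and a miRNA->gene edge (`mirna_gene`). The loop sign is the product
#' of the two edge signs: -1 is negative feedback (e.g. a gene activating a
#' miRNA that represses it), +1 positive (double repression or double
#' activation).
#'
#' @param net A `signed_regnet`.
#' @return A `data.frame` with columns `gene`, `mirna`, `sign_gene_mirna`,
#'   `sign_mirna_gene`, `loop_sign`.
#' @export
enumerate_feedback_loops <- function(net) {
  stopifnot(inherits(net, "signed_regnet"))
  e <- net$edges
  gm <- e[e$layer == "gene_mirna", c("source", "target", "sign")]
  mg <- e[e$layer == "mirna_gene", c("source", "target", "sign")]
  empty <- data.frame(gene = character(0), mirna = character(0),
                      sign_gene_mirna = integer(0),
                      sign_mirna_gene = integer(0), loop_sign = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(gm) == 0L || nrow(mg) == 0L) return(empty)
  names(gm) <- c("gene", "mirna", "sign_gene_mirna")
  names(mg) <- c("mirna", "gene", "sign_mirna_gene")
  loops <- merge(gm, mg, by = c("gene", "mirna"))
  if (nrow(loops) == 0L) return(empty)
  out <- data.frame(gene = loops$gene, mirna = loops$mirna,
                    sign_gene_mirna = loops$sign_gene_mirna,
                    sign_mirna_gene = loops$sign_mirna_gene,
                    loop_sign = loops$sign_gene_mirna * loops$sign_mirna_gene,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$mirna), , drop = FALSE]
  row.names(out) <- NULL
  out
}
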