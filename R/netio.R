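#' Read an undirected interaction network from SIF or TSV
#'
#' Parses a plain-text edge list into a simple undirected [igraph][igraph::graph]
#' object. Self-loops and duplicate edges are dropped (a message reports how
#' many), endpoint identifiers are whitespace-trimmed, and the result is
#' independent of row order.
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`tsv`}{two tab-separated columns, `nodeA<TAB>nodeB`, one edge per
#'     row. A leading `source<TAB>target` header row (as written by
#'     [write_network()]) is detected and skipped.}
#'   \item{`sif`}{Cytoscape simple interaction format:
#'     `nodeA <interaction> nodeB [nodeC ...]`. Rows with more than one target
#'     expand to a star from the first node. A single-token row declares an
#'     isolated node.}
#' }
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"sif"`.
#' @param normalize If `TRUE`, identifiers are passed through [normalize_ids()]
#'   (gene symbols upper-cased, miRNA ids canonicalised).
#' @return An undirected simple `igraph` graph.
#' @seealso [write_network()], [read_signed_edges()]
#' @export
read_network <- function(path, format = c("tsv", "sif"), normalize = FALSE) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) {
    stop("empty network file: ", path, call. = FALSE)
  }
  from <- character(0)
  to <- character(0)
  singletons <- character(0)
  first_data <- TRUE
  for (i in rows) {
    tokens <- strsplit(trimws(lines[[i]]), "\t|\\s+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (format == "tsv") {
      if (first_data && length(tokens) == 2L &&
          identical(tolower(tokens), c("source", "target"))) {
        first_data <- FALSE
        next
      }
      if (length(tokens) != 2L) {
        stop("malformed TSV edge row at line ", i, ": expected 2 fields, got ",
             length(tokens), call. = FALSE)
      }
      from <- c(from, tokens[[1]])
      to <- c(to, tokens[[2]])
    } else {
      if (length(tokens) == 1L) {
        singletons <- c(singletons, tokens[[1]])
      } else if (length(tokens) == 2L) {
        stop("malformed SIF row at line ", i,
             ": 2 tokens (source + interaction type but no target)",
             call. = FALSE)
      } else {
        targets <- tokens[3:length(tokens)]
        from <- c(from, rep(tokens[[1]], length(targets)))
        to <- c(to, targets)
      }
    }
    first_data <- FALSE
  }
  if (normalize) {
    from <- normalize_ids(from)
    to <- normalize_ids(to)
    singletons <- normalize_ids(singletons)
  }
  build_interaction_network(from, to, isolated = singletons)
}

#' Build a simple undirected network from endpoint vectors
#'
#' Order-normalises each pair, drops self-loops and duplicates, and returns an
#' undirected `igraph` graph. Used by all readers and generators so every
#' network in the package satisfies the same invariants.
#'
#' @param from,to Equal-length character vectors of edge endpoints.
#' @param isolated Optional identifiers to include as degree-0 nodes.
#' @return An undirected simple `igraph` graph.
#' @export
build_interaction_network <- function(from, to, isolated = character(0)) {
  stopifnot(length(from) == length(to))
  from <- trimws(as.character(from))
  to <- trimws(as.character(to))
  loops <- from == to
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    from <- from[!loops]
    to <- to[!loops]
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message("dropped ", sum(dup), " duplicate edge(s)")
    a <- a[!dup]
    b <- b[!dup]
  }
  nodes <- sort(unique(c(a, b, trimws(isolated))))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(a) > 0L) {
    g <- igraph::add_edges(g, rbind(match(a, nodes), match(b, nodes)))
  }
  g
}

#' Write a network as a two-column TSV with a provenance sidecar
#'
#' Emits `source<TAB>target` rows (header included) and a JSON sidecar
#' `<path>.provenance.json` recording node/edge counts, so a written file
#' round-trips through [read_network()] to an identical node and edge set.
#'
#' @param net An undirected `igraph` graph.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  df <- data.frame(source = pmin(el[, 1], el[, 2]),
                   target = pmax(el[, 1], el[, 2]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(path = path,
                  n_nodes = igraph::vcount(net),
                  n_edges = igraph::ecount(net))
  jsonlite::write_json(sidecar, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Normalise molecular identifiers
#'
#' Gene symbols are upper-cased; miRNA identifiers (any id matching an
#' `hsa-`/`miR-`/`let-` prefix, case-insensitively) are canonicalised to the
#' conventional mixed case: a lower-case `hsa-` prefix, `miR`/`let` stem, and
#' the remainder untouched (so arm/variant suffixes such as `-5p` or `133b`
#' survive as written).
#'
#' @param ids Character vector of identifiers.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_ids(c("tp53", "HSA-MIR-429", "Mir-133b", "akt1"))
normalize_ids <- function(ids) {
  ids <- trimws(as.character(ids))
  is_mirna <- grepl("^(hsa-)?(mir|let)-", ids, ignore.case = TRUE)
  out <- toupper(ids)
  if (any(is_mirna)) {
    m <- ids[is_mirna]
    m <- sub("^hsa-", "", m, ignore.case = TRUE)
    stem <- ifelse(grepl("^let-", m, ignore.case = TRUE), "let-", "miR-")
    tail <- sub("^(mir|let)-", "", m, ignore.case = TRUE)
    out[is_mirna] <- paste0("hsa-", stem, tail)
  }
  out
}

#' Layers of the signed regulatory network
#'
#' @return Character vector of the four recognised edge layers.
#' @export
regulatory_layers <- function() {
  c("tf_gene", "tf_mirna", "mirna_gene", "gene_mirna")
}

.SIGN_TOKENS <- c("activate" = 1, "activation" = 1, "+" = 1, "+1" = 1,
                  "repress" = -1, "repression" = -1, "-" = -1, "-1" = -1)

#' Read signed regulatory edges from a three-column TSV
#'
#' Rows are `source<TAB>target<TAB>sign`; sign tokens `activate`, `repress`,
#' `+`, `-`, `+1`, `-1` (plus the `activation`/`repression` long forms) map to
#' +1/-1. Any other token is rejected with the offending row number.
#'
#' @param path Path to the TSV file.
#' @param layer One of [regulatory_layers()]: which regulatory layer these
#'   edges belong to (`tf_gene`, `tf_mirna`, `mirna_gene`, `gene_mirna`).
#' @param normalize Passed to [normalize_ids()] for both endpoint columns.
#' @return A `data.frame` with columns `source`, `target`, `sign` (integer
#'   +1/-1) and `layer`.
#' @export
read_signed_edges <- function(path, layer, normalize = FALSE) {
  layer <- match.arg(layer, regulatory_layers())
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  rows <- which(!grepl("^\\s*(#|$)", lines))
  src <- tgt <- character(length(rows))
  sgn <- integer(length(rows))
  for (j in seq_along(rows)) {
    i <- rows[[j]]
    tokens <- strsplit(trimws(lines[[i]]), "\t|\\s+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) != 3L) {
      stop("malformed signed-edge row at line ", i, ": expected 3 fields",
           call. = FALSE)
    }
    s <- .SIGN_TOKENS[tolower(tokens[[3]])]
    if (is.na(s)) {
      stop("unknown sign token '", tokens[[3]], "' at line ", i, call. = FALSE)
    }
    src[[j]] <- tokens[[1]]
    tgt[[j]] <- tokens[[2]]
    sgn[[j]] <- as.integer(s)
  }
  if (normalize) {
    src <- normalize_ids(src)
    tgt <- normalize_ids(tgt)
  }
  data.frame(source = src, target = tgt, sign = sgn, layer = layer,
             stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one term per line, `id<TAB>description<TAB>member...`.
#' Duplicate members within a line are collapsed; duplicate term ids across
#' lines are an error (term ids must be unique within a collection).
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (term id -> unique members), with
#'   a `"term_names"` attribute carrying the description column.
#' @export
read_gene_sets <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  rows <- which(!grepl("^\\s*(#|$)", lines))
  sets <- list()
  descs <- character(0)
  for (i in rows) {
    tokens <- strsplit(lines[[i]], "\t")[[1]]
    tokens <- trimws(tokens)
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) < 3L) {
      stop("malformed GMT row at line ", i, ": expected >= 3 fields",
           call. = FALSE)
    }
    id <- tokens[[1]]
    if (id %in% names(sets)) {
      stop("duplicate term id '", id, "' at line ", i, call. = FALSE)
    }
    members <- unique(tokens[3:length(tokens)])
    if (length(members) == 0L) {
      stop("empty member list for term '", id, "' at line ", i, call. = FALSE)
    }
    sets[[id]] <- members
    descs[[id]] <- tokens[[2]]
  }
  attr(sets, "term_names") <- descs
  sets
}
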