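#' Over-representation analysis (hypergeometric test with BH correction)
#'
#' For each annotation term, tests whether the overlap between the query set
#' and the term's members is larger than expected under hypergeometric
#' sampling from the background. P-values are the upper tail
#' `P(X >= overlap)`; multiple testing is corrected with Benjamini-Hochberg
#' across the tested terms. The odds ratio comes from the 2x2 table
#' (in-query/in-term margins), with a Haldane 0.5 correction applied when any
#' cell is zero.
#'
#' Terms are intersected with the background before testing; by default the
#' background is the union of all annotation members (the "only annotated"
#' domain convention), and the query must lie within it.
#'
#' @param query Character vector of query identifiers.
#' @param sets Named list of term member vectors (see [read_gene_sets()]).
#' @param background Character vector; defaults to the union of all set
#'   members.
#' @param p_threshold Rows with adjusted p above this are still returned,
#'   flagged in the `significant` column (default 0.05).
#' @return A `data.frame` sorted by p ascending: `term`, `name`, `overlap`,
#'   `query_size`, `term_size`, `background_size`, `p_value`, `adjusted_p`,
#'   `odds_ratio`, `significant`.
#' @export
ora <- function(query, sets, background = NULL, p_threshold = 0.05) {
  if (length(query) == 0L) stop("empty query", call. = FALSE)
  if (length(sets) == 0L) stop("no annotation sets", call. = FALSE)
  if (is.null(background)) background <- unique(unlist(sets))
  background <- unique(trimws(background))
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  query <- unique(trimws(query))
  if (!all(query %in% background)) {
    stop("query contains ", sum(!query %in% background),
         " identifier(s) outside the background", call. = FALSE)
  }
  term_names <- attr(sets, "term_names")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(unique(sets[[id]]), background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; cc <- K - k; d <- N - K - n + k
    if (min(a, b, cc, d) == 0) {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
    or <- (a * d) / (b * cc)
    if (k == 0L) or <- 0
    data.frame(term = id,
               name = if (!is.null(term_names) && id %in% names(term_names))
                 term_names[[id]] else id,
               overlap = k, query_size = n, term_size = K,
               background_size = N, p_value = p, odds_ratio = or,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable terms within the background",
                         call. = FALSE)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$adjusted_p <= p_threshold
  out <- out[order(out$p_value, out$term),
             c("term", "name", "overlap", "query_size", "term_size",
               "background_size", "p_value", "adjusted_p", "odds_ratio",
               "significant")]
  row.names(out) <- NULL
  out
}
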