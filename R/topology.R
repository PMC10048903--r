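#' Per-node topological metrics
#'
#' Computes, for every node of an undirected simple network, the six metrics
#' used throughout the hub/bottleneck analysis:
#' \describe{
#'   \item{degree}{number of interaction partners, `k`.}
#'   \item{clustering}{local clustering coefficient
#'     `C = 2 m / (k (k - 1))`, where `m` is the number of edges among the
#'     node's neighbours; defined as 0 for nodes of degree < 2.}
#'   \item{neighborhood_connectivity}{mean degree of the node's neighbours
#'     (0 for isolated nodes).}
#'   \item{betweenness}{shortest-path betweenness, normalised by
#'     `(n - 1)(n - 2) / 2` so that values lie in `[0, 1]` (endpoints
#'     excluded).}
#'   \item{closeness}{per-component closeness
#'     `(reachable - 1) / sum of geodesic distances to reachable nodes`;
#'     0 for isolated nodes.}
#'   \item{eigenvector}{principal-eigenvector centrality of the adjacency
#'     matrix, rescaled to unit L2 norm, entries non-negative.}
#' }
#'
#' @param net An undirected simple `igraph` graph with at least one node.
#' @return A `data.frame` with one row per node, columns `node`, `degree`,
#'   `clustering`, `neighborhood_connectivity`, `betweenness`, `closeness`,
#'   `eigenvector`.
#' @export
node_metrics <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network", call. = FALSE)
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  deg <- igraph::degree(net)
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  nk <- rep(0, n)
  if (igraph::ecount(net) > 0L) {
    knn <- suppressWarnings(igraph::knn(net)$knn)
    nk[deg > 0] <- knn[deg > 0]
  }
  btw <- if (n > 2) {
    igraph::betweenness(net, directed = FALSE, normalized = TRUE)
  } else {
    rep(0, n)
  }
  clo <- rep(0, n)
  if (any(deg > 0)) {
    cl <- suppressWarnings(
      igraph::closeness(net, mode = "all", normalized = TRUE))
    clo[deg > 0] <- cl[deg > 0]
  }
  eig <- rep(0, n)
  if (igraph::ecount(net) > 0L) {
    eig <- .eigenvector_power(net)
  }
  data.frame(node = nodes, degree = as.integer(deg), clustering = cc,
             neighborhood_connectivity = nk, betweenness = btw,
             closeness = clo, eigenvector = eig,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Empirical degree distribution P(k) = N_k / N
#'
#' @param net An undirected `igraph` graph with at least one node.
#' @return Named numeric vector: names are observed degrees, values the
#'   fraction of nodes with that degree (sums to 1).
#' @export
degree_distribution_table <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network", call. = FALSE)
  tab <- table(igraph::degree(net))
  p <- as.numeric(tab) / n
  names(p) <- names(tab)
  p
}

# principal eigenvector of the adjacency matrix by shifted power iteration:
# iterating (A + I) x keeps every eigenvalue positive, so the method also
# converges on bipartite graphs (where A alone has a -lambda_max mode that
# makes plain power iteration oscillate). Deterministic uniform start,
# L2 normalisation each step, sup-norm tolerance 1e-10, at most 1000 sweeps.
.eigenvector_power <- function(net, tol = 1e-10, max_iter = 1000L) {
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  n <- nrow(A)
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    y <- as.numeric(Matrix::crossprod(A, x)) + x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) {
      x <- y
      break
    }
    x <- y
  }
  abs(x)
}

.METRIC_FIELDS <- c("degree", "clustering", "neighborhood_connectivity",
                    "betweenness", "closeness", "eigenvector")

#' Mean of a metric per degree class
#'
#' Aggregates a node-metrics table to one value per observed degree: the
#' arithmetic mean of `field` over all nodes with that degree. These
#' per-degree means are the points the log-log power-law fits operate on
#' (one point per degree, as in the standard C(k), CN(k), CB(k) plots).
#'
#' @param metrics Output of [node_metrics()].
#' @param field One of the six metric columns.
#' @return Named numeric vector mapping degree -> mean metric value.
#' @export
aggregate_by_degree <- function(metrics, field) {
  if (!field %in% .METRIC_FIELDS) {
    stop("unknown metric field '", field, "'", call. = FALSE)
  }
  means <- tapply(metrics[[field]], metrics$degree, mean)
  out <- as.numeric(means)
  names(out) <- names(means)
  out
}

#' Fit a power law by least squares on log-log axes
#'
#' Ordinary least squares of `log10(y)` on `log10(k)` over the strictly
#' positive `(k, y)` pairs of a per-degree aggregate. For a decaying law
#' `y ~ k^(-gamma)` the returned `slope` is `-gamma`. A constant `y`
#' (zero variance on the log scale) is reported with `slope = 0`,
#' `pearson_r = 0` and `degenerate = TRUE` rather than an undefined
#' correlation.
#'
#' @param agg Named numeric vector (degree -> value), e.g. from
#'   [aggregate_by_degree()] or [degree_distribution_table()].
#' @return An object of class `power_law_fit`: a list with `slope`,
#'   `intercept`, `pearson_r`, `n_points`, `degenerate`.
#' @export
fit_power_law_ols <- function(agg) {
  k <- as.numeric(names(agg))
  y <- as.numeric(agg)
  ok <- is.finite(k) & is.finite(y) & k > 0 & y > 0
  k <- k[ok]
  y <- y[ok]
  if (length(k) < 3L) {
    stop("insufficient data: need >= 3 strictly positive (k, y) points, got ",
         length(k), call. = FALSE)
  }
  lx <- log10(k)
  ly <- log10(y)
  if (stats::sd(ly) == 0) {
    fit <- list(slope = 0, intercept = mean(ly), pearson_r = 0,
                n_points = length(k), degenerate = TRUE)
    class(fit) <- "power_law_fit"
    return(fit)
  }
  co <- stats::coef(stats::lm(ly ~ lx))
  fit <- list(slope = unname(co[[2]]), intercept = unname(co[[1]]),
              pearson_r = stats::cor(lx, ly), n_points = length(k),
              degenerate = FALSE)
  class(fit) <- "power_law_fit"
  fit
}

#' @exportS3Method base::print
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit: slope %.4f, intercept %.4f, r %.4f (%d points%s)\n",
              x$slope, x$intercept, x$pearson_r, x$n_points,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Power-law fits for all degree-aggregated metrics
#'
#' Convenience wrapper fitting `P(k)` and the five per-degree metric means
#' against degree, skipping any metric with too few positive points.
#'
#' @param net An undirected `igraph` graph.
#' @param metrics Optional precomputed [node_metrics()] table.
#' @return Named list of `power_law_fit` objects, at most one per metric
#'   (`degree_distribution`, `clustering`, `neighborhood_connectivity`,
#'   `betweenness`, `closeness`, `eigenvector`).
#' @export
fit_all_power_laws <- function(net, metrics = node_metrics(net)) {
  aggs <- c(list(degree_distribution = degree_distribution_table(net)),
            lapply(stats::setNames(nm = setdiff(.METRIC_FIELDS, "degree")),
                   function(f) aggregate_by_degree(metrics, f)))
  fits <- list()
  for (nm in names(aggs)) {
    fit <- tryCatch(fit_power_law_ols(aggs[[nm]]), error = function(e) NULL)
    if (!is.null(fit)) fits[[nm]] <- fit
  }
  fits
}
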