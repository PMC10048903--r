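# Independent brute-force reference implementations used to validate the
# package's graph metrics. Deliberately naive: explicit all-pairs distance
# matrices, geodesic counting by dynamic programming over distance shells,
# and a dense eigendecomposition. Nothing here calls the code under test.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# number of geodesics between every pair, built outward by distance shell
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  NP <- matrix(0, n, n)
  diag(NP) <- 1
  for (i in seq_len(n)) {
    ds <- sort(unique(D[i, is.finite(D[i, ]) & D[i, ] > 0]))
    for (d in ds) {
      for (j in which(D[i, ] == d)) {
        pred <- which(A[, j] == 1 & D[i, ] == d - 1)
        NP[i, j] <- sum(NP[i, pred])
      }
    }
  }
  NP
}

# betweenness by explicit pair enumeration: for each interior vertex v sum
# the fraction of i-j geodesics passing through v
oracle_betweenness <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  if (n <= 2) return(rep(0, n))
  D <- oracle_distances(A)
  NP <- oracle_path_counts(A, D)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (i == v || j == v || !is.finite(D[i, j]) || NP[i, j] == 0) next
        if (D[i, v] + D[v, j] == D[i, j]) {
          acc <- acc + NP[i, v] * NP[v, j] / NP[i, j]
        }
      }
    }
    btw[v] <- acc
  }
  btw / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  D <- oracle_distances(A)
  vapply(seq_len(n), function(i) {
    r <- setdiff(which(is.finite(D[i, ])), i)
    if (length(r) == 0) 0 else length(r) / sum(D[i, r])
  }, numeric(1))
}

oracle_eigenvector <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  e <- eigen(A, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v / sqrt(sum(v^2))
}

# random connected graph on n nodes (resamples until connected)
random_connected_graph <- function(n, p = 0.5) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- paste0("v", seq_len(n))
      return(g)
    }
  }
}
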