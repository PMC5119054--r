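# Brute-force oracles for the measure battery, independent of the package
# implementation (and of igraph): Floyd-Warshall distances, geodesic
# counting by adjacency-matrix powers, and direct enumeration for
# clustering, betweenness, closeness and mean path length.

oracle_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A == 1] <- 1
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# number of geodesics between every pair: (A^L)[i, j] counts walks of
# length L, and a walk of minimal length is necessarily a path
oracle_geodesic_counts <- function(A, d = oracle_distances(A)) {
  n <- nrow(A)
  cnt <- matrix(0, n, n)
  cnt[d == 0] <- 1
  maxd <- max(c(0, d[is.finite(d) & d > 0]))
  Ak <- diag(1, n)
  for (L in seq_len(maxd)) {
    Ak <- Ak %*% A
    cnt[d == L] <- Ak[d == L]
  }
  cnt
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  d <- oracle_distances(A)
  cnt <- oracle_geodesic_counts(A, d)
  b <- numeric(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (!is.finite(d[i, j]) || d[i, j] < 2) next
      for (v in seq_len(n)) {
        if (v == i || v == j) next
        if (is.finite(d[i, v]) && is.finite(d[v, j]) &&
            d[i, v] + d[v, j] == d[i, j]) {
          b[v] <- b[v] + cnt[i, v] * cnt[v, j] / cnt[i, j]
        }
      }
    }
  }
  if (n > 2) b / ((n - 1) * (n - 2) / 2) else b
}

oracle_closeness <- function(A) {
  n <- nrow(A)
  d <- oracle_distances(A)
  vapply(seq_len(n), function(v) {
    comp <- which(is.finite(d[v, ]))
    if (length(comp) < 2) return(0)
    (length(comp) - 1) / sum(d[v, setdiff(comp, v)])
  }, numeric(1))
}

oracle_local_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(A[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, numeric(1))
}

oracle_avg_path_length <- function(A) {
  d <- oracle_distances(A)
  # largest component (ties: first)
  n <- nrow(A)
  seen <- rep(FALSE, n)
  comps <- list()
  for (v in seq_len(n)) {
    if (seen[v]) next
    members <- which(is.finite(d[v, ]))
    seen[members] <- TRUE
    comps[[length(comps) + 1]] <- members
  }
  sizes <- lengths(comps)
  lc <- comps[[which.max(sizes)]]
  dd <- d[lc, lc]
  mean(dd[upper.tri(dd)])
}

# random symmetric 0/1 adjacency matrix without loops
random_adjacency <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(runif(length(up)) < p)
  A + t(A)
}

graph_from_adjacency <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}
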