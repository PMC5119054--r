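# Binomial random-graph null model: uniform simple G(N,M) graphs with the
# same vertex and edge counts as the observed network, plus the analytic
# clustering expectation and binomial degree-distribution fits.

#' Sample a uniform G(N,M) random graph
#'
#' A simple undirected graph drawn uniformly among all graphs with exactly
#' N vertices and M edges (no loops, no multi-edges).
#'
#' @param N vertex count.
#' @param M edge count; must satisfy `M <= N (N - 1) / 2`.
#' @param seed optional integer seed; when given, sampling is reproducible
#'   and the caller's RNG state is left untouched.
#' @return an undirected igraph graph.
#' @export
sample_gnm <- function(N, M, seed = NULL) {
  if (M > N * (N - 1) / 2) {
    stop("M = ", M, " exceeds the maximum ", N * (N - 1) / 2,
         " edges for N = ", N)
  }
  draw <- function() igraph::sample_gnm(N, M, directed = FALSE, loops = FALSE)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Analytic clustering expectation for a binomial random graph
#'
#' In a G(N,M) graph the probability that any two vertices are connected is
#' p = 2M / (N (N - 1)) = c / (N - 1), where c = 2M / N is the average
#' degree; the expected clustering coefficient equals this p.
#'
#' @param c average degree.
#' @param N vertex count (>= 2).
#' @return expected clustering coefficient.
#' @export
expected_clustering <- function(c, N) {
  if (N < 2) stop("N must be >= 2")
  c / (N - 1)
}

#' Random-graph ensemble summary
#'
#' Samples `n_reps` G(N,M) replicates (per-replicate seeds drawn
#' deterministically from the master seed), computing each replicate's
#' global clustering coefficient, average path length (largest component)
#' and degree histogram.
#'
#' @param N,M matched vertex and edge counts (use the observed network's
#'   N and its distinct undirected edge count).
#' @param n_reps number of replicates (>= 1).
#' @param seed master integer seed.
#' @return list of class `random_graph_ensemble` with fields `N`, `M`, `p`,
#'   `c`, `n_reps`, `seed`, `per_rep` (data.frame: rep, C, L), `degree_counts`
#'   (pooled degree histogram over replicates), `mean_C`, `mean_L`, `se_C`,
#'   `se_L`.
#' @export
ensemble_summary <- function(N, M, n_reps = 20, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  rep_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max, n_reps))
  C <- L <- numeric(n_reps)
  pooled <- integer(0)
  for (r in seq_len(n_reps)) {
    g <- sample_gnm(N, M, seed = rep_seeds[r])
    stopifnot(igraph::ecount(g) == M, igraph::vcount(g) == N)
    C[r] <- global_clustering(g)
    L[r] <- if (M > 0) average_path_length(g) else NA_real_
    k <- igraph::degree(g)
    tab <- tabulate(k + 1L)
    if (length(tab) > length(pooled)) {
      pooled <- c(pooled, integer(length(tab) - length(pooled)))
    }
    pooled[seq_along(tab)] <- pooled[seq_along(tab)] + tab
  }
  structure(list(
    N = N, M = M,
    p = 2 * M / (N * (N - 1)),
    c = 2 * M / N,
    n_reps = n_reps, seed = seed,
    per_rep = data.frame(rep = seq_len(n_reps), C = C, L = L),
    degree_counts = data.frame(k = seq_along(pooled) - 1L, count = pooled),
    mean_C = mean(C), mean_L = mean(L),
    se_C = if (n_reps > 1) sd(C) / sqrt(n_reps) else NA_real_,
    se_L = if (n_reps > 1) sd(L) / sqrt(n_reps) else NA_real_
  ), class = "random_graph_ensemble")
}

#' @export
print.random_graph_ensemble <- function(x, ...) {
  cat("<random_graph_ensemble> G(N = ", x$N, ", M = ", x$M, "), ",
      x$n_reps, " replicates (seed ", x$seed, ")\n",
      "  mean C = ", signif(x$mean_C, 4),
      " (analytic ", signif(expected_clustering(x$c, x$N), 4), ")",
      ", mean L = ", round(x$mean_L, 3), "\n", sep = "")
  invisible(x)
}

#' Fit a binomial degree distribution
#'
#' Moment-matched binomial fit for a random-graph degree histogram: the
#' trial count is fixed at N - 1 by the model and p_hat is the mean degree
#' divided by N - 1. R^2 compares the observed degree fractions with the
#' Binomial(N - 1, p_hat) pmf over the observed support.
#'
#' @param dd a `degree_distribution` (or data.frame with `k` and `pk`).
#' @param N vertex count of the underlying graph.
#' @return list of class `binomial_fit` with `n_trials`, `p_hat`, `r2`.
#' @export
fit_binomial_degree <- function(dd, N) {
  if (!is.data.frame(dd) || !all(c("k", "pk") %in% names(dd))) {
    stop("expected a degree_distribution (columns k, pk)")
  }
  mean_k <- sum(dd$k * dd$pk)
  p_hat <- mean_k / (N - 1)
  pmf <- dbinom(dd$k, size = N - 1, prob = p_hat)
  ss_res <- sum((dd$pk - pmf)^2)
  ss_tot <- sum((dd$pk - mean(dd$pk))^2)
  r2 <- if (ss_tot == 0) as.numeric(ss_res == 0) else 1 - ss_res / ss_tot
  structure(list(n_trials = N - 1, p_hat = p_hat, r2 = r2),
            class = "binomial_fit")
}

#' @export
print.binomial_fit <- function(x, ...) {
  cat("<binomial_fit> Binomial(", x$n_trials, ", ", signif(x$p_hat, 4),
      "), R^2 = ", round(x$r2, 4), "\n", sep = "")
  invisible(x)
}
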