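# The network measure battery: clustering, path length, degree
# distributions with log-log power-law fits, betweenness and closeness.
#
# All distance/clustering/centrality measures operate on the undirected
# loop-free simple graph; degree reports in/out/total on the directed
# simple graph.

#' Local clustering coefficient
#'
#' C_i = 2 E_i / (k_i (k_i - 1)), where E_i is the number of edges among
#' the k_i neighbours of the vertex; vertices with fewer than two
#' neighbours have C_i = 0 by convention. Computed on the undirected
#' loop-free simplification.
#'
#' @param net a `syntactic_network` or igraph graph.
#' @param v vertex names (default: all vertices).
#' @return named numeric vector of C_i values in `[0, 1]`.
#' @export
local_clustering <- function(net, v = NULL) {
  u <- to_undirected_simple(net)
  if (is.null(v)) v <- igraph::V(u)$name
  if (!all(v %in% igraph::V(u)$name)) {
    stop("unknown vertex: ", paste(setdiff(v, igraph::V(u)$name), collapse = ", "))
  }
  ci <- igraph::transitivity(u, type = "local", vids = v, isolates = "zero")
  setNames(ci, v)
}

#' Global clustering coefficient
#'
#' The arithmetic mean of the local clustering coefficients over all N
#' vertices (degree < 2 vertices contribute 0).
#'
#' @param net a `syntactic_network` or igraph graph.
#' @return C in `[0, 1]`.
#' @export
global_clustering <- function(net) {
  u <- to_undirected_simple(net)
  if (igraph::vcount(u) == 0) stop("empty graph")
  igraph::transitivity(u, type = "localaverage", isolates = "zero")
}

#' Average path length
#'
#' Mean shortest-path length over all unordered vertex pairs of the
#' undirected loop-free simple graph. When the graph is disconnected, the
#' mean is taken over the largest component (deterministic tie-break, see
#' [largest_component()]).
#'
#' @param net a `syntactic_network` or igraph graph.
#' @return L >= 1 for any graph with at least one edge.
#' @export
average_path_length <- function(net) {
  u <- to_undirected_simple(net)
  if (igraph::vcount(u) < 2) stop("average path length needs >= 2 vertices")
  lc <- largest_component(u)
  if (igraph::vcount(lc) < 2) stop("largest component has < 2 vertices")
  igraph::mean_distance(lc, directed = FALSE)
}

#' Degree distribution
#'
#' Histogram of vertex degrees plus the cumulative tail P(K >= k). The
#' default mode is total degree on the directed simple loop-free graph
#' (in-degree + out-degree); `"in"` and `"out"` are available. For an
#' undirected input, all modes coincide.
#'
#' @param net a `syntactic_network` or igraph graph.
#' @param mode `"total"`, `"in"` or `"out"`.
#' @return data.frame of class `degree_distribution` with columns `k`,
#'   `count`, `pk` (fraction of vertices with degree k) and `cum`
#'   (P(K >= k)); attribute `N` holds the vertex count.
#' @export
degree_distribution <- function(net, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  g <- as_igraph(net)
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  imode <- switch(mode, total = "all", "in" = "in", out = "out")
  k <- igraph::degree(gs, mode = imode, loops = FALSE)
  tab <- table(k)
  kk <- as.integer(names(tab))
  count <- as.integer(tab)
  pk <- count / length(k)
  dd <- data.frame(k = kk, count = count, pk = pk,
                   cum = rev(cumsum(rev(pk))))
  attr(dd, "N") <- igraph::vcount(gs)
  attr(dd, "mode") <- mode
  class(dd) <- c("degree_distribution", "data.frame")
  dd
}

#' Fit a power law to the cumulative degree distribution by log-log OLS
#'
#' Ordinary least squares of log10 P(K >= k) on log10 k over all degrees
#' k >= 1 with positive tail mass (no tail truncation). A power-law degree
#' distribution P(k) ~ k^(-gamma) appears as a straight line; the fit
#' reports the slope (sign preserved), its magnitude `gamma`, the
#' intercept and the coefficient of determination R^2.
#'
#' @param dd a `degree_distribution`, or any data.frame with columns `k`
#'   and `cum`.
#' @return list of class `power_law_fit` with `slope`, `gamma`,
#'   `intercept`, `r2` and `n_points`.
#' @export
fit_power_law_loglog <- function(dd) {
  if (!is.data.frame(dd) || !all(c("k", "cum") %in% names(dd))) {
    stop("expected a degree_distribution (columns k, cum)")
  }
  pts <- dd[dd$k >= 1 & dd$cum > 0, ]
  if (length(unique(pts$k)) < 3) {
    stop("power-law fit needs >= 3 distinct positive degrees, got ",
         length(unique(pts$k)))
  }
  fit <- lm(log10(cum) ~ log10(k), data = pts)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((log10(pts$cum) - mean(log10(pts$cum)))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 gamma = -unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = 1 - ss_res / ss_tot,
                 n_points = nrow(pts)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power_law_fit> slope = ", round(x$slope, 4),
      ", R^2 = ", round(x$r2, 4), " (", x$n_points, " support points)\n",
      sep = "")
  invisible(x)
}

#' Betweenness centrality
#'
#' For vertex v, the sum over ordered-unordered pairs (i, j), i != j != v,
#' of the fraction of i-j geodesics that pass through v, normalised by
#' (N - 1)(N - 2) / 2 so that the centre of a star scores 1. Endpoints are
#' not counted as interior vertices. Computed on the undirected loop-free
#' simple graph (shortest paths ignore arc multiplicities).
#'
#' @param net a `syntactic_network` or igraph graph.
#' @return named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(net) {
  u <- to_undirected_simple(net)
  b <- igraph::betweenness(u, directed = FALSE, weights = NA,
                           normalized = FALSE)
  n <- igraph::vcount(u)
  if (n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  setNames(as.numeric(b), igraph::V(u)$name)
}

#' Closeness centrality
#'
#' (n - 1) / (sum of distances to all other vertices of the vertex's
#' component), where n is the component size. Isolated vertices get 0.
#' Computed on the undirected loop-free simple graph.
#'
#' @param net a `syntactic_network` or igraph graph.
#' @return named numeric vector in `[0, 1]`.
#' @export
closeness_centrality <- function(net) {
  u <- to_undirected_simple(net)
  cc <- suppressWarnings(igraph::closeness(u, mode = "all", weights = NA,
                                           normalized = TRUE))
  iso <- !is.finite(cc)
  if (any(iso)) {
    message(sum(iso), " isolated vertex/vertices assigned closeness 0")
    cc[iso] <- 0
  }
  setNames(as.numeric(cc), igraph::V(u)$name)
}

#' Per-vertex metric table
#'
#' One row per word type with directed degrees (in/out/total on the
#' directed simple loop-free graph), local clustering, normalised
#' betweenness, closeness, and the vertex's mean shortest-path distance to
#' the other members of its component (NA for isolated vertices).
#'
#' @param net a `syntactic_network` or igraph graph.
#' @return data.frame with columns `key`, `k_in`, `k_out`, `k_total`,
#'   `C_i`, `betweenness`, `closeness`, `mean_distance` and, when the
#'   network carries vertex POS tags, `pos`.
#' @export
vertex_metrics <- function(net) {
  g <- as_igraph(net)
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  u <- to_undirected_simple(net)
  nm <- igraph::V(gs)$name
  if (igraph::is_directed(gs)) {
    k_in <- as.integer(igraph::degree(gs, mode = "in", loops = FALSE))
    k_out <- as.integer(igraph::degree(gs, mode = "out", loops = FALSE))
    k_total <- k_in + k_out
  } else {
    k_total <- as.integer(igraph::degree(gs, loops = FALSE))
    k_in <- k_out <- rep(NA_integer_, length(k_total))
  }
  d <- igraph::distances(u, weights = NA)
  diag(d) <- NA
  mean_dist <- apply(d, 1, function(row) {
    fin <- row[is.finite(row)]
    if (length(fin) == 0) NA_real_ else mean(fin)
  })
  out <- data.frame(
    key = nm,
    k_in = k_in,
    k_out = k_out,
    k_total = k_total,
    C_i = unname(local_clustering(u)[nm]),
    betweenness = unname(betweenness_centrality(u)[nm]),
    closeness = unname(closeness_centrality(u)[nm]),
    mean_distance = unname(mean_dist[nm]),
    stringsAsFactors = FALSE
  )
  pos <- igraph::vertex_attr(g, "pos")
  if (!is.null(pos)) out$pos <- pos
  rownames(out) <- NULL
  out
}

#' Whole-network summary
#'
#' The global measure battery: N, distinct undirected edge count M,
#' distinct arc count, average degree, global clustering (over all
#' vertices, plus the largest component's value), average path length on
#' the largest component, and the component structure.
#'
#' @param net a `syntactic_network` or igraph graph.
#' @return list of class `network_summary` with `N`, `M`, `M_arcs`,
#'   `avg_degree`, `C`, `C_largest`, `L`, `n_components`, `largest_share`.
#' @export
network_summary <- function(net) {
  g <- as_igraph(net)
  u <- to_undirected_simple(net)
  comp <- component_report(u)
  lc <- largest_component(u)
  structure(list(
    N = igraph::vcount(g),
    M = igraph::ecount(u),
    M_arcs = n_arcs(g),
    avg_degree = avg_degree(g),
    C = global_clustering(u),
    C_largest = global_clustering(lc),
    L = if (igraph::vcount(lc) >= 2) average_path_length(lc) else NA_real_,
    n_components = comp$n_components,
    largest_share = comp$largest_share
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary> N = ", x$N, ", M = ", x$M,
      ", <k> = ", round(x$avg_degree, 3),
      ", C = ", round(x$C, 4), ", L = ", round(x$L, 3),
      ", components = ", x$n_components,
      " (largest ", round(100 * x$largest_share, 2), "%)\n", sep = "")
  invisible(x)
}

#' Write a vertex-metrics table or degree distribution as CSV
#'
#' @param x a data.frame (e.g. from [vertex_metrics()] or
#'   [degree_distribution()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
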