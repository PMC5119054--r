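# Construction of the word-type syntactic dependency network.
#
# Vertices are word types; a directed arc governor -> dependent is drawn for
# every dependency token pair, with repeated type pairs collapsed into a
# single arc whose multiplicity is kept as the edge weight. Root tokens
# contribute a vertex but no arc.

#' Build a syntactic dependency network from a treebank
#'
#' @param tb a `treebank`.
#' @param exclude_punct drop punctuation tokens (and any arc touching one).
#' @param punct_pos POS tags treated as punctuation.
#' @param keep_self_loops keep arcs whose governor and dependent are the
#'   same word type (they are always excluded from degree and from all
#'   distance/clustering measures, but are retained in the arc list and the
#'   Pajek export unless dropped here).
#' @param key word-type identity: surface `"form"` (default) or
#'   `"form_pos"` pairs.
#' @return An object of class `syntactic_network` wrapping a directed
#'   igraph graph with an edge `weight` attribute (the arc multiplicity)
#'   and a vertex `pos` attribute (the type's most frequent POS tag).
#' @examples
#' tb <- treebank(data.frame(
#'   sent = "s1", id = 1:2, form = c("A", "B"), pos = c("n", "v"),
#'   head = c(2L, 0L), deprel = c("subj", "root")))
#' net <- build_network(tb)
#' n_vertices(net); avg_degree(net)
#' @export
build_network <- function(tb, exclude_punct = TRUE,
                          punct_pos = punctuation_tags(),
                          keep_self_loops = TRUE,
                          key = c("form", "form_pos")) {
  stopifnot(inherits(tb, "treebank"))
  key <- match.arg(key)
  tok <- tb$tokens
  if (nrow(tok) == 0) stop("cannot build a network from an empty treebank")
  keyed <- if (key == "form") tok$form else paste(tok$form, tok$pos, sep = "/")
  # governor key of each token, NA for roots
  gov <- rep(NA_character_, nrow(tok))
  for (sid in unique(tok$sent)) {
    sel <- which(tok$sent == sid)
    s <- tok[sel, ]
    ord <- order(s$id)
    pos_of <- integer(max(s$id))
    pos_of[s$id] <- sel
    has_gov <- s$head > 0
    gov[sel[has_gov]] <- keyed[pos_of[s$head[has_gov]]]
  }
  keep <- rep(TRUE, nrow(tok))
  if (exclude_punct) {
    is_punct <- tok$pos %in% punct_pos
    punct_keys <- unique(keyed[is_punct])
    keep <- !is_punct
    gov[gov %in% punct_keys] <- NA  # arcs into/out of punctuation dropped
  }
  dep_key <- keyed[keep]
  gov_key <- gov[keep]
  if (length(dep_key) == 0) stop("no tokens left after punctuation exclusion")
  # dominant POS per type (ties: alphabetically first tag)
  pos_tab <- table(dep_key, tok$pos[keep])
  vert_pos <- colnames(pos_tab)[apply(pos_tab, 1, which.max)]
  verts <- data.frame(name = rownames(pos_tab), pos = vert_pos,
                      stringsAsFactors = FALSE)
  has_arc <- !is.na(gov_key)
  if (!keep_self_loops) has_arc <- has_arc & gov_key != dep_key
  arcs <- data.frame(from = gov_key[has_arc], to = dep_key[has_arc],
                     stringsAsFactors = FALSE)
  if (nrow(arcs) > 0) {
    agg <- stats::aggregate(list(weight = rep(1L, nrow(arcs))),
                            by = arcs, FUN = sum)
  } else {
    agg <- data.frame(from = character(), to = character(), weight = integer())
  }
  g <- igraph::graph_from_data_frame(agg, directed = TRUE, vertices = verts)
  structure(list(graph = g, name = tb$name, key = key),
            class = "syntactic_network")
}

#' @export
print.syntactic_network <- function(x, ...) {
  cat("<syntactic_network> ", x$name, ": N = ", n_vertices(x),
      ", arcs = ", n_arcs(x), " (", n_edges(x), " undirected edges), <k> = ",
      round(avg_degree(x), 3), "\n", sep = "")
  invisible(x)
}

as_igraph <- function(net) {
  if (inherits(net, "syntactic_network")) net$graph
  else if (igraph::is_igraph(net)) net
  else stop("expected a syntactic_network or an igraph graph")
}

#' Network size accessors
#'
#' `n_vertices`: number of word types; `n_arcs`: distinct directed
#' governor->dependent type pairs, self-loops excluded; `n_edges`: distinct
#' undirected edges after simplification (loops removed, reciprocal arcs
#' merged); `avg_degree`: mean total degree `2 * n_arcs / N` on the directed
#' simple loop-free graph; `self_loop_types`: word types with a
#' governor = dependent arc.
#'
#' @param net a `syntactic_network` or igraph graph.
#' @return a count (or character vector for `self_loop_types`).
#' @export
n_vertices <- function(net) igraph::vcount(as_igraph(net))

#' @rdname n_vertices
#' @export
n_arcs <- function(net) {
  g <- as_igraph(net)
  sum(!igraph::which_loop(g))
}

#' @rdname n_vertices
#' @export
n_edges <- function(net) igraph::ecount(to_undirected_simple(net))

#' @rdname n_vertices
#' @export
avg_degree <- function(net) 2 * n_arcs(net) / n_vertices(net)

#' @rdname n_vertices
#' @export
self_loop_types <- function(net) {
  g <- as_igraph(net)
  loops <- igraph::which_loop(g)
  unique(igraph::tail_of(g, igraph::E(g)[loops])$name)
}

#' Undirected loop-free simplification
#'
#' Drops arc direction, merges parallel/reciprocal arcs (summing
#' multiplicities) and removes self-loops. All distance, clustering and
#' centrality measures operate on this view.
#'
#' @param net a `syntactic_network` or igraph graph.
#' @return an undirected simple igraph graph.
#' @export
to_undirected_simple <- function(net) {
  g <- as_igraph(net)
  if (!igraph::is_directed(g)) {
    return(igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                            edge.attr.comb = list(weight = "sum", "ignore")))
  }
  u <- igraph::as_undirected(g, mode = "collapse",
                             edge.attr.comb = list(weight = "sum", "ignore"))
  igraph::simplify(u, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(weight = "sum", "ignore"))
}

#' Connected-component report
#'
#' Weak components of the undirected simplification. The largest component
#' is chosen deterministically: maximum size, ties broken by the
#' lexicographically smallest member.
#'
#' @param net a `syntactic_network` or igraph graph.
#' @return list with `n_components`, `largest_size`, `largest_share` and
#'   `sizes` (all component sizes, decreasing).
#' @export
component_report <- function(net) {
  u <- to_undirected_simple(net)
  comp <- igraph::components(u)
  idx <- largest_component_index(u, comp)
  list(n_components = comp$no,
       largest_size = comp$csize[idx],
       largest_share = comp$csize[idx] / igraph::vcount(u),
       sizes = sort(comp$csize, decreasing = TRUE))
}

largest_component_index <- function(u, comp = igraph::components(u)) {
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    nm <- igraph::V(u)$name
    first_member <- vapply(best, function(i) {
      members <- which(comp$membership == i)
      if (is.null(nm)) sprintf("%012d", min(members)) else min(nm[members])
    }, character(1))
    best <- best[order(first_member)][1]
  }
  best[1]
}

#' Largest connected component
#'
#' @param net a `syntactic_network` or igraph graph.
#' @return the largest component of the undirected simplification, as an
#'   igraph graph (ties broken as in [component_report()]).
#' @export
largest_component <- function(net) {
  u <- to_undirected_simple(net)
  comp <- igraph::components(u)
  idx <- largest_component_index(u, comp)
  igraph::induced_subgraph(u, which(comp$membership == idx))
}

#' Export a network in Pajek .net format
#'
#' Writes `*Vertices N` with 1-based ids and quoted labels, then `*Arcs`
#' (directed input) or `*Edges` lines `src dst weight`.
#'
#' @param net a `syntactic_network` or igraph graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_pajek <- function(net, path) {
  g <- as_igraph(net)
  labels <- igraph::V(g)$name
  if (is.null(labels)) labels <- as.character(seq_len(igraph::vcount(g)))
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  el <- igraph::as_edgelist(g, names = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("*Vertices %d", igraph::vcount(g)), con)
  writeLines(sprintf('%d "%s"', seq_along(labels), labels), con)
  writeLines(if (igraph::is_directed(g)) "*Arcs" else "*Edges", con)
  if (nrow(el) > 0) {
    writeLines(sprintf("%d %d %g", el[, 1], el[, 2], w), con)
  }
  invisible(path)
}

#' Read a Pajek .net file
#'
#' Minimal reader for the subset written by [export_pajek()]: a `*Vertices`
#' block with quoted labels and one `*Arcs` (directed) or `*Edges`
#' (undirected) block with optional weights.
#'
#' @param path file path.
#' @return an igraph graph with vertex names and edge weights.
#' @export
read_pajek <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  vh <- grep("^\\*Vertices", lines, ignore.case = TRUE)
  if (length(vh) != 1) stop("not a Pajek file: missing *Vertices")
  n <- as.integer(sub("^\\*Vertices\\s+(\\d+).*$", "\\1", lines[vh],
                      ignore.case = TRUE))
  eh <- grep("^\\*(Arcs|Edges)", lines, ignore.case = TRUE)
  if (length(eh) < 1) stop("not a Pajek file: missing *Arcs/*Edges")
  eh <- eh[1]
  directed <- grepl("^\\*Arcs", lines[eh], ignore.case = TRUE)
  labels <- character(n)
  for (line in lines[(vh + 1):(eh - 1)]) {
    if (grepl("^\\s*$", line)) next
    m <- regmatches(line, regexec('^\\s*(\\d+)\\s+"([^"]*)"', line))[[1]]
    if (length(m) == 3) labels[as.integer(m[2])] <- m[3]
  }
  empty <- !nzchar(labels)
  labels[empty] <- sprintf("v%d", which(empty))
  elines <- lines[seq(eh + 1, length.out = max(0, length(lines) - eh))]
  elines <- elines[!grepl("^\\s*$|^\\*", elines)]
  g <- igraph::make_empty_graph(n, directed = directed)
  igraph::V(g)$name <- labels
  if (length(elines) > 0) {
    parts <- do.call(rbind, lapply(strsplit(trimws(elines), "\\s+"), function(p) {
      c(as.numeric(p[1]), as.numeric(p[2]),
        if (length(p) >= 3) as.numeric(p[3]) else 1)
    }))
    g <- igraph::add_edges(g, t(parts[, 1:2, drop = FALSE]),
                           weight = parts[, 3])
  }
  g
}

#' Export the arc list as CSV
#'
#' Columns `src`, `dst`, `weight` (arc multiplicity).
#'
#' @param net a `syntactic_network` or igraph graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_edge_csv <- function(net, path) {
  g <- as_igraph(net)
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  df <- data.frame(src = el[, 1], dst = el[, 2], weight = w,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
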