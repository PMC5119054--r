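# Function-word analyses and the two-corpus comparison: Mann-Whitney U on
# per-vertex measure distributions, chi-square on function-word token
# shares, and Kolmogorov-Smirnov on the centralities of the function words
# shared by both networks.

#' Function-word token percentage
#'
#' P_f = 100 * n_f / N, the share of word tokens that are function words.
#'
#' @param n_function function-word token count.
#' @param n_tokens total word-token count (> 0).
#' @return percentage in `[0, 100]`.
#' @export
function_word_percentage <- function(n_function, n_tokens) {
  if (any(n_tokens <= 0)) stop("token count must be positive")
  100 * n_function / n_tokens
}

#' Function-word types shared by two networks
#'
#' Function-word status is evaluated per network from the vertex POS tags
#' (plus any explicit form list in the lexicon); the result is the
#' intersection of the two networks' function-word vertex sets.
#'
#' @param net_a,net_b `syntactic_network` objects built with the same
#'   lexicon conventions.
#' @param lex a [function_word_lexicon()].
#' @return sorted character vector of shared word types.
#' @export
shared_function_words <- function(net_a, net_b, lex = function_word_lexicon()) {
  fw <- function(net) {
    g <- as_igraph(net)
    pos <- igraph::vertex_attr(g, "pos")
    if (is.null(pos)) pos <- rep(NA_character_, igraph::vcount(g))
    igraph::V(g)$name[is_function_word(igraph::V(g)$name, pos, lex)]
  }
  sort(intersect(fw(net_a), fw(net_b)))
}

#' Function-word centrality table
#'
#' Per-vertex degree, betweenness and closeness restricted to the
#' network's function-word vertices, sorted by decreasing degree
#' (ties broken by form).
#'
#' @param net a `syntactic_network`.
#' @param lex a [function_word_lexicon()].
#' @param metrics optional precomputed [vertex_metrics()] table.
#' @return data.frame with columns `form`, `pos`, `degree`, `betweenness`,
#'   `closeness`.
#' @export
function_word_table <- function(net, lex = function_word_lexicon(),
                                metrics = NULL) {
  if (is.null(metrics)) metrics <- vertex_metrics(net)
  if (is.null(metrics$pos)) metrics$pos <- NA_character_
  sel <- is_function_word(metrics$key, metrics$pos, lex)
  out <- data.frame(form = metrics$key[sel], pos = metrics$pos[sel],
                    degree = metrics$k_total[sel],
                    betweenness = metrics$betweenness[sel],
                    closeness = metrics$closeness[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$form), ]
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum test comparing two samples. Uses exact enumeration when both
#' samples have at most 8 untied observations, and the normal
#' approximation with tie correction otherwise; the branch can be forced
#' with `exact`.
#'
#' @param x,y numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact force the exact (TRUE) or normal-approximation (FALSE)
#'   branch; NULL picks automatically.
#' @return list with `U` (the U statistic of `x`), `p_value`, `method`,
#'   `alternative`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided", exact = NULL) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- length(x) <= 8 && length(y) <= 8 && !ties
  if (exact && ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = !exact)
  )
  list(U = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation",
       alternative = alternative)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |ECDF_x - ECDF_y| with the asymptotic p-value.
#'
#' @param x,y numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `D`, `p_value`, `alternative`.
#' @export
ks_two_sample <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ht <- suppressWarnings(ks.test(x, y, alternative = alternative,
                                 exact = FALSE))
  list(D = unname(ht$statistic), p_value = ht$p.value,
       alternative = alternative)
}

#' Chi-square test on two function-word token shares
#'
#' Pearson chi-square (df = 1) on the 2x2 table of function vs
#' non-function tokens by group, without continuity correction by default.
#'
#' @param nf_a,n_a function-word and total token counts for group A.
#' @param nf_b,n_b likewise for group B.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `p_value`, `df`, `table`.
#' @export
chi_square_2x2 <- function(nf_a, n_a, nf_b, n_b, correct = FALSE) {
  tab <- rbind(A = c(fun = nf_a, other = n_a - nf_a),
               B = c(fun = nf_b, other = n_b - nf_b))
  if (any(tab < 0)) stop("negative cell count")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in the 2x2 table")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), table = tab)
}

#' Full two-corpus network comparison
#'
#' Orchestrates the whole pipeline for two treebanks: corpus statistics,
#' network construction, the measure battery, G(N,M) null ensembles,
#' small-world and scale-free verdicts, function-word tables, and the
#' group tests - Mann-Whitney U on the per-vertex distributions of degree,
#' local clustering and mean distance; chi-square on the function-word
#' token shares; Kolmogorov-Smirnov on degree, betweenness and closeness
#' of the function words shared by both networks.
#'
#' @param tb_a,tb_b `treebank` objects for the two groups.
#' @param lex a [function_word_lexicon()].
#' @param n_reps random-graph replicates per null ensemble.
#' @param seed master seed for the null ensembles.
#' @param theta_C,theta_L small-world thresholds (see [small_world_test()]).
#' @param r2_threshold scale-free threshold (see [scale_free_test()]).
#' @param exclude_punct drop punctuation tokens throughout.
#' @return list of class `comparison_report`; see the elements `stats`,
#'   `summaries`, `verdicts`, `function_words` and `tests`.
#' @export
compare_networks <- function(tb_a, tb_b, lex = function_word_lexicon(),
                             n_reps = 20, seed = 1,
                             theta_C = 10, theta_L = 1.5,
                             r2_threshold = 0.95, exclude_punct = TRUE) {
  groups <- list(a = tb_a, b = tb_b)
  stats <- lapply(groups, corpus_stats, lex = lex,
                  exclude_punct = exclude_punct)
  nets <- lapply(groups, build_network, exclude_punct = exclude_punct)
  summaries <- lapply(nets, network_summary)
  metrics <- lapply(nets, vertex_metrics)
  dds <- lapply(nets, degree_distribution)
  ens_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 2))
  ensembles <- mapply(function(s, sd) ensemble_summary(s$N, s$M, n_reps, sd),
                      summaries, ens_seeds, SIMPLIFY = FALSE)
  verdicts <- list(
    small_world = mapply(small_world_test, summaries, ensembles,
                         MoreArgs = list(theta_C = theta_C,
                                         theta_L = theta_L),
                         SIMPLIFY = FALSE),
    scale_free = lapply(dds, scale_free_test, r2_threshold = r2_threshold)
  )
  shared <- shared_function_words(nets$a, nets$b, lex)
  fw_tables <- mapply(function(n, m) function_word_table(n, lex, m),
                      nets, metrics, SIMPLIFY = FALSE)
  shared_vals <- lapply(metrics, function(m) {
    m[match(shared, m$key), c("k_total", "betweenness", "closeness")]
  })
  mwu <- lapply(c(degree = "k_total", clustering = "C_i",
                  mean_distance = "mean_distance"), function(col) {
    xa <- metrics$a[[col]]; xb <- metrics$b[[col]]
    mann_whitney_u(xa[!is.na(xa)], xb[!is.na(xb)])
  })
  ks <- lapply(c(degree = "k_total", betweenness = "betweenness",
                 closeness = "closeness"), function(col) {
    if (length(shared) == 0) return(NULL)
    ks_two_sample(shared_vals$a[[col]], shared_vals$b[[col]])
  })
  chisq <- tryCatch(
    chi_square_2x2(stats$a$function_token_count, stats$a$token_count,
                   stats$b$function_token_count, stats$b$token_count),
    error = function(e) NULL  # degenerate table (e.g. no function tokens)
  )
  structure(list(
    names = c(a = tb_a$name, b = tb_b$name),
    config = list(n_reps = n_reps, seed = seed, theta_C = theta_C,
                  theta_L = theta_L, r2_threshold = r2_threshold,
                  exclude_punct = exclude_punct,
                  lexicon = unclass(lex)),
    stats = stats,
    summaries = summaries,
    ensembles = ensembles,
    degree_distributions = dds,
    verdicts = verdicts,
    function_words = list(shared = shared,
                          n_shared = length(shared),
                          tables = fw_tables,
                          shared_means = lapply(shared_vals, function(v) {
                            if (length(shared) == 0) return(NULL)
                            c(degree = mean(v$k_total),
                              betweenness = mean(v$betweenness),
                              closeness = mean(v$closeness))
                          })),
    tests = list(mann_whitney = mwu, ks_shared_fw = ks, chi_square = chisq)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$names["a"], " vs ", x$names["b"], "\n", sep = "")
  for (gr in c("a", "b")) {
    s <- x$stats[[gr]]; ns <- x$summaries[[gr]]
    cat(sprintf("  %s: %d tokens, %d types (TTR %.3f), P_f %.1f%% | N %d, <k> %.3f, C %.4f, L %.3f\n",
                x$names[gr], s$token_count, s$type_count, s$ttr,
                s$function_word_pct, ns$N, ns$avg_degree, ns$C, ns$L))
    cat(sprintf("     small-world: %s, scale-free: %s (R^2 %.4f)\n",
                x$verdicts$small_world[[gr]]$is_small_world,
                x$verdicts$scale_free[[gr]]$is_scale_free,
                x$verdicts$scale_free[[gr]]$fit$r2))
  }
  cat("  shared function words:", x$function_words$n_shared, "\n")
  if (!is.null(x$tests$chi_square)) {
    cat(sprintf("  chi-square (P_f): X^2 = %.2f, p = %.3g\n",
                x$tests$chi_square$statistic, x$tests$chi_square$p_value))
  }
  for (nm in names(x$tests$mann_whitney)) {
    t <- x$tests$mann_whitney[[nm]]
    cat(sprintf("  MWU %-13s p = %.3g\n", nm, t$p_value))
  }
  for (nm in names(x$tests$ks_shared_fw)) {
    t <- x$tests$ks_shared_fw[[nm]]
    if (!is.null(t)) cat(sprintf("  KS  %-13s D = %.3f, p = %.3g\n",
                                 nm, t$D, t$p_value))
  }
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' Serialises everything except the raw ensembles' per-replicate degree
#' histograms.
#'
#' @param report a `comparison_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  strip <- rapply(unclass(report), f = identity, how = "replace")
  strip$ensembles <- lapply(report$ensembles, function(e) {
    e <- unclass(e); e$degree_counts <- NULL; e
  })
  jsonlite::write_json(strip, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
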