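# Function-word statistics and the two-group nonparametric tests.

test_that("function-word percentage follows the token-share formula", {
  expect_equal(round(function_word_percentage(4824, 20986)), 23)
  expect_equal(function_word_percentage(0, 100), 0)
  expect_equal(function_word_percentage(100, 100), 100)
  expect_error(function_word_percentage(1, 0), "positive")
})

test_that("shared function words are the intersection of both vertex sets", {
  sim <- small_preset_pair()
  net_a <- build_network(sim$a)
  net_b <- build_network(sim$b)
  lex <- function_word_lexicon()
  shared <- shared_function_words(net_a, net_b, lex)
  expect_gt(length(shared), 0)
  expect_true(all(shared %in% igraph::V(net_a$graph)$name))
  expect_true(all(shared %in% igraph::V(net_b$graph)$name))
  # identical networks share all their function-word vertices
  self_shared <- shared_function_words(net_a, net_a, lex)
  tab <- function_word_table(net_a, lex)
  expect_setequal(self_shared, tab$form)
  # disjoint vocabularies share nothing
  mk <- function(forms) treebank(data.frame(
    sent = "s1", id = 1:2, form = forms, pos = c("p", "n"),
    head = c(2L, 0L), deprel = c("case", "root")))
  expect_length(shared_function_words(build_network(mk(c("zai", "jia"))),
                                      build_network(mk(c("cong", "xiao"))),
                                      lex),
                0)
})

test_that("function-word table rows carry the vertex metrics", {
  sim <- small_preset_pair()
  net <- build_network(sim$a)
  lex <- function_word_lexicon()
  m <- vertex_metrics(net)
  tab <- function_word_table(net, lex, metrics = m)
  expect_true(all(is_function_word(tab$form, tab$pos, lex)))
  expect_true(all(diff(tab$degree) <= 0))
  i <- match(tab$form[1], m$key)
  expect_equal(tab$degree[1], m$k_total[i])
  expect_equal(tab$betweenness[1], m$betweenness[i])
})

test_that("Mann-Whitney U matches exact enumeration on separated samples", {
  # all 20 rank assignments enumerated by hand: U = 0, one-sided p = 1/20
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 20)
  expect_equal(r$method, "exact")
  # identical samples: two-sided approximate p = 1
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  # a large shift is detected
  withr::with_seed(41, {
    x <- rnorm(200)
    y <- rnorm(200) + 1
  })
  expect_lt(mann_whitney_u(x, y)$p_value, 0.001)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact and approximate MWU branches agree for n = 8 vs 8", {
  withr::with_seed(43, {
    for (i in 1:20) {
      x <- sample(1:1000, 8)
      y <- sample(1001:2000, 4) + runif(4)  # no ties by construction
      y <- c(y, sample(seq(0.5, 500.5, by = 1), 4))
      p_exact <- mann_whitney_u(x, y, exact = TRUE)$p_value
      p_approx <- mann_whitney_u(x, y, exact = FALSE)$p_value
      expect_lt(abs(p_exact - p_approx), 0.02)
    }
  })
})

test_that("Kolmogorov-Smirnov D matches a direct ECDF scan", {
  expect_equal(ks_two_sample(1:10, 1:10)$D, 0)
  expect_equal(ks_two_sample(1:5, 6:10)$D, 1)
  withr::with_seed(47, {
    for (i in 1:10) {
      x <- rnorm(20); y <- rnorm(25, 0.5)
      grid <- sort(c(x, y))
      d_oracle <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
      expect_equal(ks_two_sample(x, y)$D, d_oracle, tolerance = 1e-12)
    }
  })
})

test_that("chi-square on the 2x2 function-word table matches the closed form", {
  flat <- chi_square_2x2(10, 20, 10, 20)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # hand-computed Pearson value for [[5,15],[15,5]]
  hand <- chi_square_2x2(5, 20, 15, 20)
  expect_equal(hand$statistic, 10)
  # the printed group counts differ significantly
  printed <- chi_square_2x2(3539, 21141, 4824, 20986)
  expect_lt(printed$p_value, 0.001)
  # symmetric in the two groups
  swapped <- chi_square_2x2(4824, 20986, 3539, 21141)
  expect_equal(swapped$statistic, printed$statistic)
  expect_equal(swapped$p_value, printed$p_value)
  expect_error(chi_square_2x2(0, 0, 1, 2), "marginal")
})

test_that("compare_networks produces a full, consistent report", {
  sim <- small_preset_pair()
  rep <- compare_networks(sim$a, sim$b, n_reps = 3, seed = 5)
  expect_s3_class(rep, "comparison_report")
  expect_equal(rep$stats$a$token_count,
               corpus_stats(sim$a)$token_count)
  # shared function-word means equal the per-vertex table means
  shared <- rep$function_words$shared
  for (gr in c("a", "b")) {
    m <- vertex_metrics(build_network(sim[[gr]]))
    sel <- m[match(shared, m$key), ]
    expect_equal(unname(rep$function_words$shared_means[[gr]]["degree"]),
                 mean(sel$k_total))
    expect_equal(unname(rep$function_words$shared_means[[gr]]["closeness"]),
                 mean(sel$closeness))
  }
  expect_named(rep$tests$mann_whitney,
               c("degree", "clustering", "mean_distance"))
  expect_named(rep$tests$ks_shared_fw,
               c("degree", "betweenness", "closeness"))
  expect_true(all(vapply(rep$tests$mann_whitney,
                         function(t) t$p_value >= 0 && t$p_value <= 1,
                         logical(1))))
})

test_that("comparing a treebank with itself finds no differences", {
  tb <- small_preset_pair()$a
  rep <- compare_networks(tb, tb, n_reps = 2, seed = 5)
  expect_equal(rep$tests$chi_square$statistic, 0)
  for (t in rep$tests$mann_whitney) expect_gt(t$p_value, 0.9)
  for (t in rep$tests$ks_shared_fw) expect_equal(t$D, 0)
  expect_equal(rep$stats$a, rep$stats$b)
})

test_that("the worked-example treebank runs end to end", {
  tb <- example_treebank()
  rep <- compare_networks(tb, tb, n_reps = 2, seed = 5)
  expect_equal(rep$summaries$a$N, 6)
  expect_equal(rep$function_words$n_shared, 0)
  expect_null(rep$tests$ks_shared_fw$degree)
})
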