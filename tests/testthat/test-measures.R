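# The measure battery against closed forms and brute-force oracles.

test_that("local clustering matches closed forms on canonical graphs", {
  k3 <- igraph::make_full_graph(3)
  expect_equal(unname(local_clustering(k3)), rep(1, 3))
  star <- igraph::make_star(5, mode = "undirected")
  expect_equal(unname(local_clustering(star)), rep(0, 5))
  # vertex v with neighbours {a, b, c} and exactly edge (a, b) among them
  g <- igraph::graph_from_literal(v - a, v - b, v - c, a - b)
  expect_equal(unname(local_clustering(g, "v")), 1 / 3)
  expect_error(local_clustering(g, "nope"), "unknown vertex")
})

test_that("global clustering is the mean of local values over all vertices", {
  expect_equal(global_clustering(igraph::make_full_graph(4)), 1)
  expect_equal(global_clustering(igraph::make_tree(10, mode = "undirected")), 0)
  # triangle plus one pendant vertex: C_i = 1, 1, 1/3, 0 -> mean 7/12
  g <- igraph::graph_from_literal(a - b, b - c, a - c, c - d)
  expect_equal(unname(local_clustering(g)[c("a", "b", "c", "d")]),
               c(1, 1, 1 / 3, 0))
  expect_equal(global_clustering(g), mean(c(1, 1, 1 / 3, 0)))
})

test_that("average path length matches hand enumeration", {
  path3 <- igraph::make_ring(3, circular = FALSE)
  expect_equal(average_path_length(path3), 4 / 3)
  expect_equal(average_path_length(igraph::make_full_graph(6)), 1)
  # disconnected: computed on the largest component only
  g <- igraph::graph_from_literal(a - b, b - c, d - e)
  expect_equal(average_path_length(g), 4 / 3)
  expect_error(average_path_length(igraph::make_empty_graph(1)), ">= 2")
})

test_that("betweenness and closeness match closed forms on stars and paths", {
  star <- igraph::make_star(5, mode = "undirected")  # centre is vertex 1
  b <- unname(betweenness_centrality(star))
  expect_equal(b[1], 1)
  expect_equal(b[-1], rep(0, 4))
  cc <- unname(closeness_centrality(star))
  expect_equal(cc[1], 1)
  expect_equal(cc[-1], rep(4 / 7, 4))
  path3 <- igraph::make_ring(3, circular = FALSE)
  expect_equal(unname(betweenness_centrality(path3))[2], 1)
  expect_equal(unname(closeness_centrality(igraph::make_full_graph(7))),
               rep(1, 7))
})

test_that("isolated vertices get closeness 0", {
  g <- igraph::add_vertices(igraph::make_full_graph(3), 1)
  expect_message(cc <- closeness_centrality(g), "isolated")
  expect_equal(unname(cc), c(1, 1, 1, 0))
})

test_that("measures match brute-force enumeration on random graphs", {
  withr::with_seed(421, {
    for (rep in 1:50) {
      n <- sample(4:12, 1)
      A <- random_adjacency(n, runif(1, 0.15, 0.7))
      g <- graph_from_adjacency(A)
      expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(A),
                   tolerance = 1e-9)
      expect_equal(unname(closeness_centrality(g)), oracle_closeness(A),
                   tolerance = 1e-9)
      expect_equal(unname(local_clustering(g)), oracle_local_clustering(A),
                   tolerance = 1e-9)
      if (sum(A) > 0) {
        expect_equal(average_path_length(g), oracle_avg_path_length(A),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("betweenness mass is conserved over pairs", {
  # sum of unnormalised betweenness = sum over pairs of (geodesic length - 1)
  # weighted by geodesic shares; check via the oracle's pair decomposition
  withr::with_seed(99, {
    for (rep in 1:10) {
      n <- sample(5:10, 1)
      A <- random_adjacency(n, 0.4)
      d <- oracle_distances(A)
      fin <- is.finite(d) & upper.tri(d)
      expected_total <- sum(pmax(d[fin] - 1, 0))
      b <- oracle_betweenness(A) * if (n > 2) (n - 1) * (n - 2) / 2 else 1
      expect_equal(sum(b), expected_total, tolerance = 1e-9)
    }
  })
})

test_that("degree distribution normalises and has a non-increasing tail", {
  net <- build_network(example_treebank())
  dd <- degree_distribution(net)
  expect_s3_class(dd, "degree_distribution")
  expect_equal(sum(dd$pk), 1)
  expect_equal(dd$cum[1], 1)
  expect_true(all(diff(dd$cum) <= 0))
  # hand count on the worked example: degrees This 2, Is 2, An 1,
  # Example 4, Very 1, Convincing 2
  m <- vertex_metrics(net)
  expect_equal(setNames(m$k_total, m$key)[c("Example", "An", "Is")],
               c(Example = 4, An = 1, Is = 2))
  expect_equal(sum(dd$count), 6)
  # in/out modes
  expect_equal(sum(degree_distribution(net, "in")$pk), 1)
  # regular ring: single spike with cum 1
  ring <- degree_distribution(igraph::make_ring(8))
  expect_equal(nrow(ring), 1)
  expect_equal(ring$k, 2)
  expect_equal(ring$cum, 1)
  # edgeless graph: all mass at k = 0
  none <- degree_distribution(igraph::make_empty_graph(4, directed = FALSE))
  expect_equal(none$k, 0)
  expect_equal(none$pk, 1)
})

test_that("degree distributions hold their invariants on generated corpora", {
  sim <- small_preset_pair()
  for (tb in sim) {
    dd <- degree_distribution(build_network(tb))
    expect_equal(sum(dd$pk), 1)
    expect_true(all(diff(dd$cum) <= 0))
    expect_equal(dd$cum[1], 1)
    expect_equal(sum(dd$count), attr(dd, "N"))
  }
})

test_that("log-log OLS recovers an exact power-law tail", {
  dd <- data.frame(k = 1:100, cum = (1:100)^(-1.5))
  fit <- fit_power_law_loglog(dd)
  expect_equal(fit$slope, -1.5, tolerance = 1e-9)
  expect_equal(fit$gamma, 1.5, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # uniform-degree graphs have too few support points
  expect_error(fit_power_law_loglog(degree_distribution(igraph::make_ring(8))),
               "3 distinct")
})

test_that("Zipf-corpus networks fit a power law better than G(N,M) graphs", {
  sim <- small_preset_pair()
  net <- build_network(sim$a)
  fit_net <- fit_power_law_loglog(degree_distribution(net))
  g <- sample_gnm(n_vertices(net), n_edges(net), seed = 5)
  fit_rand <- fit_power_law_loglog(degree_distribution(g))
  expect_gt(fit_net$r2, fit_rand$r2)
})

test_that("network_summary is internally consistent", {
  net <- build_network(example_treebank())
  s <- network_summary(net)
  expect_equal(s$N, 6)
  expect_equal(s$M, 6)
  expect_equal(s$avg_degree, 2)
  expect_equal(s$C, global_clustering(net))
  expect_equal(s$L, average_path_length(net))
  expect_gte(s$L, 1)
  expect_equal(s$n_components, 1)
})
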