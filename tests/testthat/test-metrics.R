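# Closed-form checks on tiny hand-built digraphs, then oracle equivalence on
# random digraphs (the large seeded sweep lives in the acceptance suite).

test_that("density, components and fragmentation on hand-built graphs", {
  nodes5 <- sprintf("v%d", 1:5)
  full <- expand.grid(from = nodes5, to = nodes5, stringsAsFactors = FALSE)
  full <- full[full$from != full$to, ]
  complete5 <- net_from_edges(nodes5, full$from, full$to)
  expect_equal(net_density(complete5), 1)
  expect_equal(fragmentation(complete5), 0)
  expect_equal(unname(component_pcts(complete5)), c(100, 100, 0))

  empty10 <- net_from_edges(sprintf("v%d", 1:10))
  expect_equal(net_density(empty10), 0)
  expect_equal(fragmentation(empty10), 1)
  expect_equal(unname(component_pcts(empty10)), c(10, 10, 100))

  six <- net_from_edges(sprintf("v%d", 1:5), c("v1", "v1", "v2", "v3", "v4", "v5"),
                        c("v2", "v3", "v3", "v4", "v5", "v1"))
  expect_equal(net_density(six), 6 / 20)

  # directed path: singleton SCCs, one spanning WCC
  path3 <- net_from_edges(c("A", "B", "C"), c("A", "B"), c("B", "C"))
  expect_equal(max(graph_components(path3, "strong")), 3L)
  expect_equal(max(tabulate(graph_components(path3, "strong"))), 1L)
  expect_equal(max(tabulate(graph_components(path3, "weak"))), 3L)

  # directed 6-cycle: one SCC of 6
  cyc <- net_from_edges(sprintf("v%d", 1:6), sprintf("v%d", 1:6),
                        sprintf("v%d", c(2:6, 1)))
  expect_equal(max(tabulate(graph_components(cyc, "strong"))), 6L)

  # components {3, 2} in N = 5: fragmentation 1 - 8/20
  two_comp <- net_from_edges(sprintf("v%d", 1:5), c("v1", "v2", "v4"),
                             c("v2", "v3", "v5"))
  expect_equal(fragmentation(two_comp), 0.6)
  # directed path components: SCCs are singletons
  expect_equal(unname(component_pcts(two_comp)), c(60, 20, 0))

  # path + 2 isolates
  p2i <- net_from_edges(sprintf("v%d", 1:5), c("v1", "v2"), c("v2", "v3"))
  expect_equal(unname(component_pcts(p2i)), c(60, 20, 40))
  expect_error(net_density(net_from_edges("v1")), "at least 2")
})

test_that("centralities on hand-built graphs match closed forms", {
  # star: centre attacks all 8 others
  star <- net_from_edges(sprintf("v%d", 1:9), rep("v1", 8), sprintf("v%d", 2:9))
  expect_equal(unname(degree_centrality(star, "out")["v1"]), 1)
  expect_equal(unname(degree_centrality(star, "in")["v1"]), 0)
  expect_equal(unname(degree_centrality(star, "in")["v2"]), 1 / 8)
  expect_equal(unname(closeness_centrality(star, "out")["v1"]), 1)
  expect_equal(unname(closeness_centrality(star, "in")["v1"]), 0)

  nodes5 <- sprintf("v%d", 1:5)
  full <- expand.grid(from = nodes5, to = nodes5, stringsAsFactors = FALSE)
  full <- full[full$from != full$to, ]
  complete5 <- net_from_edges(nodes5, full$from, full$to)
  expect_equal(unname(closeness_centrality(complete5, "in")), rep(1, 5))
  expect_equal(unname(betweenness_centrality(complete5)), rep(0, 5))

  # directed path A->B->C: B carries the single geodesic
  path3 <- net_from_edges(c("A", "B", "C"), c("A", "B"), c("B", "C"))
  expect_equal(unname(betweenness_centrality(path3)), c(0, 0.5, 0))

  # isolates score zero everywhere
  p2i <- net_from_edges(sprintf("v%d", 1:5), c("v1", "v2"), c("v2", "v3"))
  for (f in list(function(n) degree_centrality(n, "in"),
                 function(n) degree_centrality(n, "out"),
                 function(n) closeness_centrality(n, "in"),
                 function(n) closeness_centrality(n, "out"),
                 betweenness_centrality))
    expect_equal(unname(f(p2i)[c("v4", "v5")]), c(0, 0))
  expect_error(betweenness_centrality(net_from_edges(c("A", "B"), "A", "B")),
               "at least 3")
})

test_that("all metrics agree with brute-force oracles on random digraphs", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    rd <- rand_digraph(n)
    net <- rd$net; A <- rd$A
    expect_equal(net_density(net), sum(A) / (n * (n - 1)), tolerance = 1e-12)
    for (mode in c("weak", "strong")) {
      got <- graph_components(net, mode)
      want <- oracle_components(A, mode)
      # same partition up to component relabelling
      expect_equal(outer(got, got, `==`), outer(want, want, `==`),
                   ignore_attr = TRUE)
    }
    expect_equal(fragmentation(net), oracle_fragmentation(A), tolerance = 1e-12)
    expect_equal(unname(degree_centrality(net, "in")), unname(colSums(A)) / (n - 1))
    expect_equal(unname(degree_centrality(net, "out")), unname(rowSums(A)) / (n - 1))
    expect_equal(unname(closeness_centrality(net, "out")),
                 oracle_closeness(A, "out"), tolerance = 1e-9)
    expect_equal(unname(closeness_centrality(net, "in")),
                 oracle_closeness(A, "in"), tolerance = 1e-9)
    expect_equal(unname(betweenness_centrality(net)), oracle_betweenness(A),
                 tolerance = 1e-9)
    # independent library cross-check on the same graph
    g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
    expect_equal(unname(betweenness_centrality(net)),
                 unname(igraph::betweenness(g, directed = TRUE)) / ((n - 1) * (n - 2)),
                 tolerance = 1e-9)
    expect_equal(max(tabulate(graph_components(net, "strong"))),
                 max(igraph::components(g, "strong")$csize))
  }
})

test_that("structural identities hold on random digraphs", {
  set.seed(88)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    rd <- rand_digraph(n)
    net <- rd$net
    # each edge contributes once to in- and once to out-degree
    expect_equal(mean(degree_centrality(net, "in")),
                 mean(degree_centrality(net, "out")))
    # fragmentation consistent with the weak-component sizes
    sizes <- tabulate(graph_components(net, "weak"))
    expect_equal(fragmentation(net),
                 1 - sum(sizes * (sizes - 1)) / (n * (n - 1)))
    # removing edges never increases density nor decreases fragmentation
    if (nrow(net$edges) >= 2) {
      sub <- net
      drop <- sample(nrow(net$edges), ceiling(nrow(net$edges) / 3))
      sub$edges <- net$edges[-drop, , drop = FALSE]
      expect_lte(net_density(sub), net_density(net))
      expect_gte(fragmentation(sub), fragmentation(net))
    }
  }
})

test_that("metrics_table assembles consistent rows", {
  empty <- net_from_edges(sprintf("v%d", 1:6))
  mt <- metrics_table(empty, "ALL", 1)
  expect_equal(mt$metrics$density, 0)
  expect_equal(mt$metrics$fragmentation, 1)
  expect_true(all(mt$centrality[, c("in_degree", "out_degree", "in_closeness",
                                    "out_closeness", "betweenness")] == 0))
  log <- simulate_pen(generator_config(lambda0 = 0.3), "p1", seed = 9)
  net <- build_network(log, "p1")
  mt1 <- metrics_table(net, "ALL", 28)
  mt2 <- metrics_table(net, "ALL", 28)
  expect_identical(mt1, mt2)  # deterministic assembly
  expect_gte(mt1$metrics$largest_wcc_pct, mt1$metrics$largest_scc_pct)
})
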