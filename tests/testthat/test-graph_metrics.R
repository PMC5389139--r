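test_that("density is 1 on cliques, 0 on edgeless graphs, and matches the edge-count formula", {
  expect_equal(net_density(bn_from_adj(adj_complete(6))), 1)
  expect_equal(net_density(bn_from_adj(adj_edgeless(5))), 0)
  expect_error(net_density(bn_from_adj(adj_edgeless(1))), "at least 2")
  # a 555-node graph with 2,911 edges has density ~0.019 (reported as 0.02)
  expect_equal(2 * 2911 / (555 * 554), 0.01893, tolerance = 1e-3)
})

test_that("global clustering matches exhaustive triple/triangle enumeration", {
  expect_equal(global_clustering(bn_from_adj(adj_complete(3))), 1)
  expect_equal(global_clustering(bn_from_adj(adj_path(3))), 0)
  expect_true(is.na(global_clustering(bn_from_adj(adj_edgeless(4)))))
  for (seed in 1:30) {
    adj <- adj_random(sample(4:12, 1), 0.4, seed = seed)
    expect_equal(global_clustering(bn_from_adj(adj)), oracle_transitivity(adj),
                 info = paste("seed", seed))
  }
})

test_that("normalized betweenness matches brute-force path enumeration", {
  star <- node_centralities(bn_from_adj(adj_star(6)))
  expect_equal(star$betweenness[star$node == "v1"], 1)
  expect_equal(star$betweenness[star$node != "v1"], rep(0, 5))

  cyc <- node_centralities(bn_from_adj(adj_cycle(6)))
  expect_true(all(abs(cyc$betweenness - cyc$betweenness[1]) < 1e-12))

  for (seed in 1:12) {
    adj <- adj_random(sample(4:8, 1), 0.45, seed = 100 + seed)
    got <- node_centralities(bn_from_adj(adj))
    expect_equal(got$betweenness, oracle_betweenness(adj), tolerance = 1e-10,
                 info = paste("seed", seed))
    expect_equal(got$degree, unname(rowSums(adj)))
  }
})

test_that("Freeman centralization is 1 on stars, 0 on cliques, and matches the formula", {
  star <- bn_from_adj(adj_star(7))
  expect_equal(graph_centralization(star, "degree"), 1)
  expect_equal(graph_centralization(star, "betweenness"), 1)
  clique <- bn_from_adj(adj_complete(5))
  expect_equal(graph_centralization(clique, "degree"), 0)
  expect_equal(graph_centralization(clique, "betweenness"), 0)
  expect_error(graph_centralization(bn_from_adj(adj_complete(2)), "degree"),
               "at least 3")
  for (seed in 1:10) {
    adj <- adj_random(sample(4:8, 1), 0.5, seed = 200 + seed)
    expect_equal(graph_centralization(bn_from_adj(adj), "degree"),
                 oracle_centralization(adj, "degree"), tolerance = 1e-10)
    expect_equal(graph_centralization(bn_from_adj(adj), "betweenness"),
                 oracle_centralization(adj, "betweenness"), tolerance = 1e-10)
  }
})

test_that("degree assortativity matches endpoint-degree correlation; regular graphs are undefined", {
  expect_equal(degree_assortativity(bn_from_adj(adj_star(8))), -1)
  expect_true(is.na(degree_assortativity(bn_from_adj(adj_cycle(6)))))
  expect_true(is.na(degree_assortativity(bn_from_adj(adj_edgeless(4)))))
  for (seed in 1:15) {
    adj <- adj_random(sample(5:9, 1), 0.45, seed = 300 + seed)
    got <- degree_assortativity(bn_from_adj(adj))
    want <- oracle_assortativity(adj)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-10, info = paste("seed", seed))
  }
})

test_that("path metrics ignore unreachable pairs", {
  p4 <- path_metrics(bn_from_adj(adj_path(4)))
  expect_equal(p4$diameter, 3)
  expect_equal(p4$avg_path_length, 10 / 6)

  k5 <- path_metrics(bn_from_adj(adj_complete(5)))
  expect_equal(k5$diameter, 1)
  expect_equal(k5$avg_path_length, 1)

  # triangle plus an isolated node: identical to the bare triangle
  tri_iso <- rbind(cbind(adj_complete(3), 0), 0)
  expect_equal(path_metrics(bn_from_adj(tri_iso)),
               path_metrics(bn_from_adj(adj_complete(3))))

  for (seed in 1:10) {
    adj <- adj_random(sample(4:8, 1), 0.35, seed = 400 + seed)
    got <- path_metrics(bn_from_adj(adj))
    want <- oracle_path_metrics(adj)
    expect_equal(got, want, tolerance = 1e-10, info = paste("seed", seed))
    if (!is.na(got$diameter)) {
      expect_gte(got$diameter, got$avg_path_length)
    }
  }
})

test_that("threshold sweeps report density 1 at tau 0 and monotone edge counts", {
  tm <- random_target_map(12, 30, 0.35, seed = 17)
  w <- build_weighted_network(tm)
  sweep <- threshold_sweep(w, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(sweep$density[sweep$tau == 0], 1)
  expect_true(all(diff(sweep$n_edges) <= 0))
  expect_equal(sweep$n_nodes, rep(12L, 5))
  expect_true(all(sweep$n_connected_nodes <= sweep$n_nodes))
  expect_error(threshold_sweep(w, c(0.5, 0.2)), "increasing")
  expect_error(threshold_sweep(w, c(0, 1.5)), "\\[0, 1\\]")
})

test_that("reference graphs have exact size and are seed-reproducible", {
  er <- reference_graph("erdos_renyi_gnm", n = 551, m = 2911, seed = 13)
  expect_equal(igraph::vcount(er$graph), 551)
  expect_equal(igraph::ecount(er$graph), 2911)
  expect_error(reference_graph("erdos_renyi_gnm", n = 5, m = 100, seed = 1),
               "infeasible")

  ba <- reference_graph("barabasi_albert", n = 40, seed = 3, m_attach = 1)
  expect_equal(igraph::ecount(ba$graph), 39)

  er2 <- reference_graph("erdos_renyi_gnm", n = 551, m = 2911, seed = 13)
  expect_identical(igraph::as_edgelist(er$graph), igraph::as_edgelist(er2$graph))
})

test_that("power-law fits are exact on exact power laws and degenerate inputs error", {
  # degree sequence whose histogram is exactly 144 * k^-2 for k = 1..4
  deg <- rep(1:4, times = c(144, 36, 16, 9))
  # a perfect fit makes summary.lm warn about its own reliability
  fit <- suppressWarnings(power_law_fit(deg))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$exponent, -2, tolerance = 1e-12)

  reg <- bn_from_adj(adj_cycle(8))
  expect_error(power_law_fit(reg), "at least 3")
})

test_that("scale-free graphs fit a power law better than same-size random graphs", {
  wins <- 0L
  for (seed in 1:50) {
    ba <- reference_graph("barabasi_albert", n = 150, seed = seed, m_attach = 1)
    m <- igraph::ecount(ba$graph)
    er <- reference_graph("erdos_renyi_gnm", n = 150, m = m, seed = seed + 1000)
    r2_ba <- tryCatch(power_law_fit(ba)$r_squared, error = function(e) NA)
    r2_er <- tryCatch(power_law_fit(er)$r_squared, error = function(e) NA)
    if (!is.na(r2_ba) && (is.na(r2_er) || r2_ba > r2_er)) wins <- wins + 1L
  }
  expect_gte(wins, 45L)
})
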