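test_that("degree ranking is a deterministic total order with lexicographic ties", {
  star <- rank_by_degree(bn_from_adj(adj_star(6)))
  expect_equal(star$node[1], "v1")

  # two nodes of equal degree: id order decides
  tie <- rank_by_degree(bn_from_adj(adj_path(2)))
  expect_equal(tie$node, c("v1", "v2"))

  for (seed in 1:5) {
    adj <- adj_random(8, 0.4, seed = 500 + seed)
    got <- rank_by_degree(bn_from_adj(adj))
    deg <- stats::setNames(rowSums(adj), paste0("v", 1:8))
    want <- names(deg)[order(-deg, names(deg))]
    expect_equal(got$node, want)
    expect_true(all(diff(got$degree) <= 0))
  }
})

test_that("the induced density curve matches brute-force induced subgraphs", {
  clique <- bn_from_adj(adj_complete(6))
  expect_equal(induced_density_curve(clique)$density, rep(1, 5))
  edgeless <- bn_from_adj(adj_edgeless(5))
  expect_equal(induced_density_curve(edgeless)$density, rep(0, 4))
  expect_error(induced_density_curve(clique, k_max = 1), "at least 2")
  expect_error(induced_density_curve(clique, k_max = 10), "exceeds")

  for (seed in 1:5) {
    adj <- adj_random(8, 0.45, seed = 600 + seed)
    bn <- bn_from_adj(adj)
    rk <- rank_by_degree(bn)
    curve <- induced_density_curve(bn, rk)
    for (r in seq_len(nrow(curve))) {
      idx <- match(rk$node[seq_len(curve$k[r])], paste0("v", 1:8))
      expect_equal(curve$density[r], oracle_induced_density(adj, idx))
    }
  }
})

test_that("a single clique is one club containing all nodes at density 1", {
  res <- detect_assorted_clubs(bn_from_adj(adj_complete(7)))
  expect_equal(res$k, 7L)
  expect_length(res$clubs, 1)
  expect_equal(res$clubs[[1]]$members, paste0("v", 1:7))
  expect_equal(res$clubs[[1]]$internal_density, 1)
  expect_true(res$clubs[[1]]$confirmed)
})

test_that("two planted cliques with top degrees are recovered exactly", {
  # cliques of sizes 5 (v1..v5) and 3 (v6..v8) on 20 nodes; background empty
  n <- 20L
  adj <- adj_edgeless(n)
  adj[1:5, 1:5] <- adj_complete(5)
  adj[6:8, 6:8] <- adj_complete(3)
  res <- detect_assorted_clubs(bn_from_adj(adj))
  expect_equal(res$k, 8L)
  expect_length(res$clubs, 2)
  expect_equal(res$clubs[[1]]$members, paste0("v", 1:5))
  expect_equal(res$clubs[[2]]$members, paste0("v", 6:8))
  expect_equal(res$clubs[[1]]$internal_density, 1)
  expect_equal(res$clubs[[2]]$internal_density, 1)
  expect_equal(res$clubs[[1]]$hub_rank_span, c(1, 5))
})

test_that("an edgeless graph yields no clubs rather than an error", {
  res <- detect_assorted_clubs(bn_from_adj(adj_edgeless(6)))
  expect_length(res$clubs, 0)
  expect_true(is.na(res$k))
})

test_that("a fixed hub count overrides the stopping rule", {
  n <- 20L
  adj <- adj_edgeless(n)
  adj[1:5, 1:5] <- adj_complete(5)
  adj[6:8, 6:8] <- adj_complete(3)
  res <- detect_assorted_clubs(bn_from_adj(adj), k_fixed = 5)
  expect_equal(res$k, 5L)
  expect_length(res$clubs, 1)
  expect_equal(res$clubs[[1]]$members, paste0("v", 1:5))
  expect_error(detect_assorted_clubs(bn_from_adj(adj), k_fixed = 1), "k_fixed")
})

test_that("clubs are vertex-disjoint and denser than the background graph", {
  for (seed in 1:20) {
    sim <- generate_prediction_table(synthetic_config(
      n_mirnas = 60, n_genes = 600,
      clubs = list(list(n_members = 6, pool_size = 120, pool_prob = 0.9),
                   list(n_members = 3, pool_size = 120, pool_prob = 0.9)),
      n_hub_genes = 10, seed = seed
    ))
    bn <- threshold_network(build_weighted_network(sim$target_map), 0.5)
    res <- detect_assorted_clubs(bn)
    members <- unlist(lapply(res$clubs, `[[`, "members"))
    expect_equal(anyDuplicated(members), 0L)
    for (cl in res$clubs) {
      expect_gte(cl$internal_density, net_density(bn))
    }
  }
})

test_that("sphere partitioning labels every node exactly once by club adjacency", {
  # clubs {v1,v2} and {v3,v4}; v5 touches club1, v6 touches club2,
  # v7 touches both, v8 touches neither club but has an edge, v9 isolated
  adj <- adj_edgeless(9)
  adj[1, 2] <- adj[2, 1] <- 1L
  adj[3, 4] <- adj[4, 3] <- 1L
  adj[5, 1] <- adj[1, 5] <- 1L
  adj[6, 3] <- adj[3, 6] <- 1L
  adj[7, 2] <- adj[2, 7] <- 1L
  adj[7, 4] <- adj[4, 7] <- 1L
  adj[8, 5] <- adj[5, 8] <- 1L
  bn <- bn_from_adj(adj)
  part <- partition_spheres(bn, list(c("v1", "v2"), c("v3", "v4")))
  labels <- stats::setNames(part$label, part$node)
  expect_equal(unname(labels[c("v5", "v6", "v7", "v8", "v9")]),
               c("sphere1", "sphere2", "intermediate", "unassigned", "isolated"))
  expect_equal(unname(labels[c("v1", "v3")]), c("club1", "club2"))
  expect_equal(nrow(part), 9L)
  expect_equal(sum(table(part$label)), 9L)
})

test_that("overlapping clubs are rejected", {
  bn <- bn_from_adj(adj_complete(4))
  expect_error(partition_spheres(bn, list(c("v1", "v2"), c("v2", "v3"))),
               "disjoint")
})

test_that("sphere labels equal brute-force adjacency checks on random graphs", {
  for (seed in 1:8) {
    adj <- adj_random(10, 0.3, seed = 700 + seed)
    bn <- bn_from_adj(adj)
    club1 <- c("v1", "v2")
    club2 <- c("v3", "v4")
    part <- partition_spheres(bn, list(club1, club2))
    labels <- stats::setNames(part$label, part$node)
    for (i in 5:10) {
      v <- paste0("v", i)
      t1 <- any(adj[i, 1:2] > 0)
      t2 <- any(adj[i, 3:4] > 0)
      want <- if (t1 && t2) "intermediate" else if (t1) "sphere1" else
        if (t2) "sphere2" else if (sum(adj[i, ]) > 0) "unassigned" else "isolated"
      expect_equal(unname(labels[v]), want, info = paste("seed", seed, v))
    }
    expect_equal(sum(table(labels)), 10L)
  }
})
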