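test_that("consensus at fraction 1 is the exact intersection of the group", {
  tm <- random_target_map(6, 20, 0.4, seed = 21)
  grp <- names(tm$entries)[1:3]
  cs <- consensus_targets(tm, grp, 1.0)
  expect_equal(cs$genes, sort(Reduce(intersect, tm$entries[grp])))
})

test_that("the member threshold is the ceiling of fraction times group size", {
  tm <- random_target_map(6, 20, 0.4, seed = 22)
  grp3 <- names(tm$entries)[1:3]
  expect_equal(consensus_targets(tm, grp3, 0.5)$min_count, 2L)
  # thresholds used for clubs and spheres of 8, 129 and 89 members
  expect_equal(ceiling(0.5 * 8), 4)
  expect_equal(ceiling(0.25 * 129), 33)
  expect_equal(ceiling(0.25 * 89), 23)
  expect_error(consensus_targets(tm, c(grp3, "nope"), 0.5), "nope")
  expect_error(consensus_targets(tm, grp3, 0), "fraction")
})

test_that("consensus sets equal brute-force per-gene counting and shrink with fraction", {
  for (seed in 1:5) {
    tm <- random_target_map(9, 25, 0.35, seed = 800 + seed)
    grp <- names(tm$entries)[1:7]
    prev <- NULL
    for (fr in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
      cs <- consensus_targets(tm, grp, fr)
      counts <- vapply(tm$universe, function(g) {
        sum(vapply(tm$entries[grp], function(set) g %in% set, logical(1)))
      }, integer(1))
      want <- sort(names(counts)[counts >= ceiling(fr * length(grp))])
      expect_equal(cs$genes, want, info = paste("seed", seed, "fr", fr))
      if (!is.null(prev)) expect_true(all(cs$genes %in% prev))
      prev <- cs$genes
    }
  }
})

test_that("gene hubs use a strict cutoff at the empirical quantile", {
  # all genes targeted equally: strict '>' leaves the hub set empty
  tm_eq <- target_map(data.frame(
    mirna = rep(c("m1", "m2"), each = 3),
    gene = rep(c("g1", "g2", "g3"), 2)
  ))
  expect_length(gene_hubs(tm_eq)$genes, 0)

  for (seed in 1:5) {
    tm <- random_target_map(15, 40, 0.3, seed = 900 + seed)
    gh <- gene_hubs(tm, quantile = 0.9)
    counts <- summarize_targeting(tm)$gene_mirna_counts
    cutoff <- unname(stats::quantile(counts, 0.9, type = 7))
    expect_equal(gh$cutoff_count, cutoff)
    expect_equal(gh$genes, sort(names(counts)[counts > cutoff]))
  }
})

test_that("hub overlap p-values equal exhaustive hypergeometric enumeration", {
  universe <- sprintf("g%02d", 1:20)
  study <- universe[1:5]
  hubs <- universe[c(1:4)]
  res <- hub_overlap_test(study, hubs, universe)
  expect_equal(res$overlap, 4L)
  expect_equal(res$expected, 5 * 4 / 20)
  expect_equal(res$p_value, oracle_hyper_p(4, 5, 4, 20), tolerance = 1e-12)

  # full-universe degenerate case
  all_in <- hub_overlap_test(universe, universe, universe)
  expect_equal(all_in$p_value, 1)
  expect_equal(all_in$overlap, 20L)

  # random small instances, exhaustive check
  set.seed(31)
  for (rep in 1:20) {
    n_u <- sample(8:25, 1)
    u <- sprintf("u%02d", seq_len(n_u))
    st <- sample(u, sample(1:n_u, 1))
    hb <- sample(u, sample(1:n_u, 1))
    res <- hub_overlap_test(st, hb, u)
    expect_equal(res$p_value,
                 oracle_hyper_p(res$overlap, length(st), length(hb), n_u),
                 tolerance = 1e-12)
  }
  expect_error(hub_overlap_test("x", "x", character(0)), "universe")
})

test_that("under-represented overlaps give one-sided enrichment p of at least 0.5", {
  universe <- sprintf("g%02d", 1:20)
  res <- hub_overlap_test(universe[1:10], universe[11:20], universe)
  expect_gte(res$p_value, 0.5)
})

toy_annotation <- function() {
  genes <- sprintf("g%02d", 1:10)
  annotation_table(
    gene2term = data.frame(
      gene = c(genes[1:3], genes[4:8], genes[1:10]),
      term = c(rep("T1", 3), rep("T2", 5), rep("T3", 10))
    ),
    term_meta = data.frame(
      term = c("T1", "T2", "T3"),
      name = c("alpha", "beta", "gamma"),
      namespace = c("BP", "BP", "BP")
    )
  )
}

test_that("a study equal to one term's genes ranks that term first with the enumerated p", {
  ann <- toy_annotation()
  universe <- sprintf("g%02d", 1:10)
  res <- go_enrichment(universe[1:3], ann, universe, namespace = "BP",
                       size_filter = NULL)
  expect_equal(res$term_id[1], "T1")
  expect_equal(res$p_classic[1], oracle_hyper_p(3, 3, 3, 10), tolerance = 1e-12)
  expect_equal(res$annotated[res$term_id == "T1"], 3L)
  expect_equal(res$significant[res$term_id == "T1"], 3L)
  expect_true(all(res$p_bh >= res$p_classic))
})

test_that("a study equal to the universe is never enriched", {
  ann <- toy_annotation()
  universe <- sprintf("g%02d", 1:10)
  res <- go_enrichment(universe, ann, universe, namespace = "BP",
                       size_filter = NULL)
  expect_true(all(res$p_classic == 1))
})

test_that("the BP size filter excludes boundary terms from the output and the BH count", {
  genes <- sprintf("g%05d", 1:6000)
  ann <- annotation_table(
    gene2term = data.frame(
      gene = c(genes[1:5000], genes[1:20], genes[1:10]),
      term = c(rep("BIG", 5000), rep("MID", 20), rep("TINY", 10))
    ),
    term_meta = data.frame(
      term = c("BIG", "MID", "TINY"),
      name = c("big", "mid", "tiny"),
      namespace = "BP"
    )
  )
  res <- go_enrichment(genes[1:20], ann, genes, namespace = "BP")
  # BIG is annotated to exactly 5,000 genes ("less than 5,000" excludes it);
  # TINY to exactly 10 ("more than 10" excludes it); only MID is tested
  expect_equal(res$term_id, "MID")
  expect_equal(res$p_bh, res$p_classic) # BH over a single tested term
})

test_that("annotated counts are computed against the restricted universe", {
  ann <- toy_annotation()
  universe <- sprintf("g%02d", 1:5) # T3 has 10 annotations, 5 in universe
  res <- go_enrichment(universe[1:2], ann, universe, namespace = "BP",
                       size_filter = NULL)
  expect_equal(res$annotated[res$term_id == "T3"], 5L)
  expect_error(go_enrichment("not-a-gene", ann, universe), "universe")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 4)), rep(0.07, 4))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  for (rep in 1:10) {
    p <- stats::runif(sample(3:40, 1))
    got <- bh_adjust(p)
    expect_equal(got, oracle_bh(p), tolerance = 1e-12)
    sorted <- sort(p)
    expect_true(all(diff(bh_adjust(sorted)) >= -1e-15))
    expect_true(all(got <= 1))
  }
})
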