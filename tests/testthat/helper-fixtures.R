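# Graph and target-map fixtures built in code.

# binary_network from a 0/1 adjacency matrix (vertices named v1..vn)
bn_from_adj <- function(adj) {
  n <- nrow(adj)
  dimnames(adj) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
  binary_network(g)
}

adj_complete <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L; a
}

adj_star <- function(n) {
  a <- matrix(0L, n, n)
  a[1L, 2:n] <- 1L; a[2:n, 1L] <- 1L
  a
}

adj_cycle <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a[i, j] <- a[j, i] <- 1L
  }
  a
}

adj_path <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) a[i, i + 1L] <- a[i + 1L, i] <- 1L
  a
}

adj_edgeless <- function(n) matrix(0L, n, n)

# seeded Erdos-Renyi-style adjacency for oracle comparisons
adj_random <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- as.integer(stats::runif(sum(up)) < p)
  a + t(a)
}

# seeded random target_map over given miRNA/gene pools
random_target_map <- function(n_mirnas, n_genes, p, seed) {
  set.seed(seed)
  mirnas <- sprintf("m%02d", seq_len(n_mirnas))
  genes <- sprintf("g%02d", seq_len(n_genes))
  hit <- matrix(stats::runif(n_mirnas * n_genes) < p, n_mirnas, n_genes)
  # ensure no empty target set
  for (i in which(rowSums(hit) == 0L)) hit[i, sample.int(n_genes, 1L)] <- TRUE
  idx <- which(hit, arr.ind = TRUE)
  target_map(data.frame(mirna = mirnas[idx[, 1L]], gene = genes[idx[, 2L]]),
             source_label = "fixture")
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
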