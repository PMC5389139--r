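# Independent brute-force reference implementations used as test oracles.
# These deliberately avoid igraph and the package's own code paths: they
# work on plain adjacency matrices with exhaustive enumeration, so they are
# only usable on small graphs.

oracle_density <- function(adj) {
  n <- nrow(adj)
  sum(adj[upper.tri(adj)]) / (n * (n - 1) / 2)
}

# transitivity = 3 * triangles / connected triples, both counted by
# exhaustive enumeration over vertex triples
oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  triangles <- 0L
  triples <- 0L
  for (j in seq_len(n)) {
    nb <- which(adj[j, ] > 0)
    others <- setdiff(nb, j)
    if (length(others) >= 2L) {
      pairs <- utils::combn(others, 2L)
      triples <- triples + ncol(pairs)
    }
  }
  if (n >= 3L) {
    cmb <- utils::combn(n, 3L)
    for (c_ in seq_len(ncol(cmb))) {
      i <- cmb[1L, c_]; j <- cmb[2L, c_]; k <- cmb[3L, c_]
      if (adj[i, j] && adj[j, k] && adj[i, k]) triangles <- triangles + 1L
    }
  }
  if (triples == 0L) return(NA_real_)
  3 * triangles / triples
}

# all simple paths between s and t by depth-first enumeration
.all_simple_paths <- function(adj, s, t) {
  paths <- list()
  recurse <- function(v, visited) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- visited
      return(invisible(NULL))
    }
    for (w in which(adj[v, ] > 0)) {
      if (!(w %in% visited)) recurse(w, c(visited, w))
    }
  }
  recurse(s, s)
  paths
}

# betweenness by enumerating every shortest path and crediting interior
# vertices fractionally; normalized by (n-1)(n-2)/2
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- .all_simple_paths(adj, s, t)
      if (length(paths) == 0L) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / sigma
      }
    }
  }
  if (n > 2L) btw <- btw / ((n - 1) * (n - 2) / 2)
  btw
}

# Freeman centralization from raw degree / normalized betweenness values
oracle_centralization <- function(adj, which) {
  n <- nrow(adj)
  if (which == "degree") {
    deg <- rowSums(adj)
    sum(max(deg) - deg) / ((n - 1) * (n - 2))
  } else {
    btw <- oracle_betweenness(adj) # normalized to [0, 1]
    sum(max(btw) - btw) / (n - 1)
  }
}

# Pearson correlation over the expanded edge-endpoint degree list
oracle_assortativity <- function(adj) {
  deg <- rowSums(adj)
  idx <- which(adj > 0 & upper.tri(adj), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NA_real_)
  x <- c(deg[idx[, 1L]], deg[idx[, 2L]])
  y <- c(deg[idx[, 2L]], deg[idx[, 1L]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# all-pairs shortest distances by Floyd-Warshall; unreachable pairs ignored
oracle_path_metrics <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
  if (length(finite) == 0L) {
    return(list(diameter = NA_real_, avg_path_length = NA_real_))
  }
  list(diameter = max(finite), avg_path_length = mean(finite))
}

oracle_meet_min <- function(a, b) {
  length(intersect(unique(a), unique(b))) / min(length(unique(a)), length(unique(b)))
}

oracle_induced_density <- function(adj, idx) {
  oracle_density(adj[idx, idx, drop = FALSE])
}

# hypergeometric upper tail by explicit summation of the density
oracle_hyper_p <- function(overlap, n_study, n_hubs, n_universe) {
  j <- overlap:min(n_study, n_hubs)
  sum(choose(n_hubs, j) * choose(n_universe - n_hubs, n_study - j)) /
    choose(n_universe, n_study)
}

# Benjamini-Hochberg step-up applied by hand
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj_sorted <- p[ord] * n / seq_len(n)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(n)
  out[ord] <- adj_sorted
  out
}
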