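#' Edge density of a binary network
#'
#' The fraction of realized edges among the n(n-1)/2 possible ones.
#'
#' @param g a `binary_network` or igraph object with at least 2 nodes
#' @return ratio in \[0, 1\]
#' @export
net_density <- function(g) {
  gr <- as_graph(g)
  n <- igraph::vcount(gr)
  if (n < 2L) stop("density requires at least 2 nodes", call. = FALSE)
  2 * igraph::ecount(gr) / (n * (n - 1))
}

#' Global clustering coefficient (transitivity)
#'
#' Triangle-based transitivity: 3 times the number of triangles divided by
#' the number of connected triples. Returns `NA` when the graph has no
#' connected triple.
#'
#' @param g a `binary_network` or igraph object
#' @return ratio in \[0, 1\], or `NA`
#' @export
global_clustering <- function(g) {
  val <- igraph::transitivity(as_graph(g), type = "global")
  if (is.nan(val)) NA_real_ else val
}

#' Per-node degree and normalized betweenness centrality
#'
#' Betweenness is computed on unweighted shortest paths with fractional
#' credit for equal-length paths and normalized by (n-1)(n-2)/2, so a star
#' center scores 1 and leaves score 0.
#'
#' @param g a `binary_network` or igraph object
#' @return data.frame (node, degree, betweenness)
#' @export
node_centralities <- function(g) {
  gr <- as_graph(g)
  n <- igraph::vcount(gr)
  btw <- igraph::betweenness(gr, directed = FALSE, weights = NA)
  if (n > 2L) btw <- btw / ((n - 1) * (n - 2) / 2)
  data.frame(
    node = igraph::V(gr)$name,
    degree = as.integer(igraph::degree(gr)),
    betweenness = as.numeric(btw),
    stringsAsFactors = FALSE
  )
}

#' Freeman graph-level centralization
#'
#' Summarizes how dominated the network is by its most central node:
#' the sum of differences between the maximum node centrality and each
#' node's centrality, divided by the theoretical maximum of that sum
#' (attained by the star graph). 1 for a star, 0 when all nodes are equally
#' central.
#'
#' @param g a `binary_network` or igraph object with at least 3 nodes
#' @param which `"degree"` or `"betweenness"`
#' @return ratio in \[0, 1\]
#' @export
graph_centralization <- function(g, which = c("degree", "betweenness")) {
  which <- match.arg(which)
  gr <- as_graph(g)
  if (igraph::vcount(gr) < 3L) {
    stop("centralization requires at least 3 nodes", call. = FALSE)
  }
  n <- igraph::vcount(gr)
  if (which == "degree") {
    # Freeman's formula with the star graph as the maximizer: a star center
    # has degree n-1 and each of the n-1 leaves contributes a difference of
    # n-2, so the denominator is (n-1)(n-2)
    deg <- igraph::degree(gr)
    sum(max(deg) - deg) / ((n - 1) * (n - 2))
  } else {
    igraph::centr_betw(gr, directed = FALSE, normalized = TRUE)$centralization
  }
}

#' Degree assortativity coefficient
#'
#' Pearson correlation of the degrees found at the two endpoints of each
#' edge (each undirected edge contributing both orientations). Negative
#' values mark disassortative networks where low-degree nodes attach
#' preferentially to high-degree ones. `NA` when the graph has no edges or
#' all degrees are equal (zero variance).
#'
#' @param g a `binary_network` or igraph object
#' @return value in \[-1, 1\], or `NA`
#' @export
degree_assortativity <- function(g) {
  gr <- as_graph(g)
  if (igraph::ecount(gr) == 0L) return(NA_real_)
  val <- suppressWarnings(igraph::assortativity_degree(gr, directed = FALSE))
  if (is.nan(val)) NA_real_ else val
}

#' Diameter and average shortest-path length
#'
#' Computed over pairs at finite distance only: unreachable pairs (between
#' components) are ignored rather than treated as infinite, so a graph with
#' isolated nodes still reports the path metrics of its connected parts.
#'
#' @param g a `binary_network` or igraph object
#' @return list (diameter, avg_path_length); both `NA` when no pair of
#'   nodes is reachable
#' @export
path_metrics <- function(g) {
  gr <- as_graph(g)
  if (igraph::ecount(gr) == 0L) {
    return(list(diameter = NA_real_, avg_path_length = NA_real_))
  }
  list(
    diameter = as.numeric(igraph::diameter(gr, directed = FALSE,
                                           unconnected = TRUE, weights = NA)),
    avg_path_length = igraph::mean_distance(gr, directed = FALSE,
                                            unconnected = TRUE)
  )
}

#' Sweep a weighted network over a grid of meet/min thresholds
#'
#' Thresholds the weighted network at each value of `taus` and records the
#' graph properties used for threshold selection. The default grid (0 to 1
#' in steps of 0.01) resolves connectivity breakpoints to two decimals.
#'
#' @param w a `weighted_simnet`
#' @param taus strictly increasing numeric grid within \[0, 1\]
#' @return data.frame with one row per tau and columns `tau`, `n_nodes`,
#'   `n_connected_nodes`, `n_edges`, `density`, `global_clustering`,
#'   `degree_centralization`, `betweenness_centralization`, `assortativity`,
#'   `diameter`, `avg_path_length`
#' @export
threshold_sweep <- function(w, taus = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(w, "weighted_simnet"))
  if (any(taus < 0) || any(taus > 1)) {
    stop("tau grid must lie within [0, 1]", call. = FALSE)
  }
  if (is.unsorted(taus, strictly = TRUE)) {
    stop("tau grid must be strictly increasing", call. = FALSE)
  }
  rows <- lapply(taus, function(tau) {
    bn <- threshold_network(w, tau)
    gr <- bn$graph
    n <- igraph::vcount(gr)
    deg <- igraph::degree(gr)
    pm <- path_metrics(bn)
    data.frame(
      tau = tau,
      n_nodes = n,
      n_connected_nodes = sum(deg > 0L),
      n_edges = igraph::ecount(gr),
      density = net_density(bn),
      global_clustering = global_clustering(bn),
      degree_centralization = if (n >= 3L) graph_centralization(bn, "degree") else NA_real_,
      betweenness_centralization = if (n >= 3L) graph_centralization(bn, "betweenness") else NA_real_,
      assortativity = degree_assortativity(bn),
      diameter = pm$diameter,
      avg_path_length = pm$avg_path_length
    )
  })
  do.call(rbind, rows)
}

#' Reference random graphs for property comparison
#'
#' Generates either an Erdős–Rényi G(n, m) graph with exactly `m` edges or
#' a Barabási–Albert preferential-attachment graph with `m_attach` edges
#' added per new node; both reproducible under `seed`.
#'
#' @param kind `"erdos_renyi_gnm"` or `"barabasi_albert"`
#' @param n number of nodes
#' @param m number of edges (G(n, m) only)
#' @param seed integer seed
#' @param m_attach edges added per step in the Barabási–Albert growth
#'   (default 1, which grows a tree)
#' @return a `binary_network` (with `threshold_used = NA`)
#' @export
reference_graph <- function(kind = c("erdos_renyi_gnm", "barabasi_albert"),
                            n, m = NULL, seed = 1L, m_attach = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  gr <- with_seed(seed, {
    if (kind == "erdos_renyi_gnm") {
      if (is.null(m) || m < 0 || m > n * (n - 1) / 2) {
        stop(sprintf("infeasible edge count m = %s for n = %d nodes",
                     format(m), n), call. = FALSE)
      }
      igraph::sample_gnm(n, m, directed = FALSE)
    } else {
      igraph::sample_pa(n, m = m_attach, directed = FALSE)
    }
  })
  igraph::V(gr)$name <- paste0("v", seq_len(n))
  binary_network(gr, threshold_used = NA_real_)
}

#' Power-law fit of the degree distribution
#'
#' Ordinary least squares of log10(frequency) on log10(degree) over the
#' non-zero-degree, non-zero-frequency bins of the raw degree histogram.
#' The slope estimates the power-law exponent; R-squared measures how
#' scale-free the degree distribution looks.
#'
#' @param g a `binary_network`, an igraph object, or a numeric vector of
#'   node degrees
#' @return list (exponent, r_squared)
#' @export
power_law_fit <- function(g) {
  deg <- if (is.numeric(g)) g else igraph::degree(as_graph(g))
  tab <- table(deg[deg > 0L])
  k <- as.numeric(names(tab))
  freq <- as.numeric(tab)
  if (length(k) < 3L) {
    stop("power-law fit needs at least 3 distinct non-zero degree frequencies",
         call. = FALSE)
  }
  fit <- stats::lm(log10(freq) ~ log10(k))
  list(
    exponent = unname(stats::coef(fit)[2L]),
    r_squared = summary(fit)$r.squared
  )
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
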