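#' Meet/min (Simpson) overlap index of two gene sets
#'
#' The proportion of shared elements relative to the smaller set:
#' `|A intersect B| / min(|A|, |B|)`. Equals 1 whenever one set contains the
#' other and 0 when the sets are disjoint; symmetric in its arguments.
#'
#' @param set_a,set_b character vectors (duplicates ignored)
#' @return a ratio in \[0, 1\]
#' @export
meet_min <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("meet/min is undefined for an empty set", call. = FALSE)
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Build the pairwise meet/min similarity network of a target map
#'
#' One node per miRNA; every unordered pair of miRNAs carries a weight equal
#' to the meet/min index of their target-gene sets, so an n-node map yields
#' n(n-1)/2 weighted pairs. Intersection sizes are computed by sparse
#' incidence-matrix algebra and kept as integer counts alongside the ratio
#' weights, so that thresholding can be decided on exact counts rather than
#' floating-point ratios.
#'
#' @param tm a `target_map` with at least two miRNAs, all with non-empty
#'   target sets
#' @return an object of class `weighted_simnet` with components `nodes`
#'   (character), `set_sizes` (integer, per node), `inter` (integer matrix of
#'   pairwise intersection sizes) and `weights` (numeric matrix of meet/min
#'   values, `NA` on the diagonal)
#' @export
build_weighted_network <- function(tm) {
  stopifnot(inherits(tm, "target_map"))
  sizes <- vapply(tm$entries, length, integer(1))
  if (length(sizes) < 2L) {
    stop("need at least 2 miRNAs to build a similarity network", call. = FALSE)
  }
  empty <- names(sizes)[sizes == 0L]
  if (length(empty) > 0L) {
    stop(sprintf("miRNAs with empty target sets: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  nodes <- names(tm$entries)
  genes <- tm$universe
  sc <- tm$site_counts
  inc <- Matrix::sparseMatrix(
    i = match(sc$mirna, nodes),
    j = match(sc$gene, genes),
    x = 1,
    dims = c(length(nodes), length(genes))
  )
  inter <- as.matrix(Matrix::tcrossprod(inc))
  storage.mode(inter) <- "integer"
  dimnames(inter) <- list(nodes, nodes)
  mins <- outer(sizes, sizes, pmin)
  weights <- inter / mins
  diag(weights) <- NA_real_
  structure(
    list(nodes = nodes, set_sizes = sizes, inter = inter, weights = weights),
    class = "weighted_simnet"
  )
}

#' @export
print.weighted_simnet <- function(x, ...) {
  n <- length(x$nodes)
  cat(sprintf("weighted_simnet: %d nodes, %d weighted pairs\n",
              n, n * (n - 1L) / 2L))
  invisible(x)
}

#' Extract the weighted pair list of a similarity network
#'
#' @param w a `weighted_simnet`
#' @return data.frame (node_a, node_b, weight) with one row per unordered
#'   pair, n(n-1)/2 rows in total
#' @export
sim_pairs <- function(w) {
  stopifnot(inherits(w, "weighted_simnet"))
  n <- length(w$nodes)
  idx <- which(upper.tri(w$weights), arr.ind = TRUE)
  data.frame(
    node_a = w$nodes[idx[, 1L]],
    node_b = w$nodes[idx[, 2L]],
    weight = w$weights[idx],
    stringsAsFactors = FALSE
  )
}

#' Write a weighted similarity network as 3-column TSV
#' @param w a `weighted_simnet`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_weighted_network <- function(w, path) {
  utils::write.table(sim_pairs(w), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Binarize a weighted similarity network at a meet/min threshold
#'
#' Keeps an edge between two miRNAs iff their meet/min weight is at least
#' `tau` (inclusive comparison). All nodes are retained, so nodes whose every
#' weight falls below `tau` become isolated. The comparison is evaluated on
#' the integer intersection counts (`count >= tau * min_size`) to avoid
#' floating-point boundary artifacts at thresholds such as 0.5.
#'
#' @param w a `weighted_simnet`
#' @param tau threshold in \[0, 1\]
#' @return an object of class `binary_network`: a named list with `graph`
#'   (an undirected [igraph::graph] whose vertices carry the miRNA names)
#'   and `threshold_used`
#' @export
threshold_network <- function(w, tau) {
  stopifnot(inherits(w, "weighted_simnet"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1) {
    stop("threshold tau must be a single value in [0, 1]", call. = FALSE)
  }
  mins <- outer(w$set_sizes, w$set_sizes, pmin)
  keep <- w$inter >= tau * mins
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = w$nodes[idx[, 1L]], to = w$nodes[idx[, 2L]]),
    directed = FALSE,
    vertices = data.frame(name = w$nodes)
  )
  binary_network(g, threshold_used = tau)
}

#' Wrap an igraph object as a binary miRNA network
#'
#' @param graph an undirected, simple [igraph::graph] with named vertices
#' @param threshold_used the meet/min threshold that produced it (or `NA`)
#' @return an object of class `binary_network`
#' @export
binary_network <- function(graph, threshold_used = NA_real_) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) stop("graph must be undirected", call. = FALSE)
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  structure(list(graph = graph, threshold_used = threshold_used),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary_network: %d nodes, %d edges (threshold %s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              format(x$threshold_used)))
  invisible(x)
}

# accept a binary_network or a bare igraph in every metric/club operation
as_graph <- function(x) {
  if (inherits(x, "binary_network")) return(x$graph)
  if (igraph::is_igraph(x)) return(x)
  stop("expected a binary_network or an igraph object", call. = FALSE)
}

#' Edge list of a binary network
#' @param g a `binary_network` or igraph object
#' @return data.frame (node_a, node_b)
#' @export
network_edges <- function(g) {
  el <- igraph::as_edgelist(as_graph(g), names = TRUE)
  data.frame(node_a = el[, 1L], node_b = el[, 2L], stringsAsFactors = FALSE)
}
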