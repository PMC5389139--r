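#' Rank network nodes by degree
#'
#' Hubs sorted by decreasing degree; ties broken lexicographically by node
#' id so the order is a deterministic total order.
#'
#' @param g a `binary_network` or igraph object
#' @return data.frame (node, degree, rank) of class `hub_ranking`
#' @export
rank_by_degree <- function(g) {
  gr <- as_graph(g)
  deg <- igraph::degree(gr)
  nodes <- igraph::V(gr)$name
  ord <- order(-deg, nodes)
  out <- data.frame(
    node = nodes[ord],
    degree = as.integer(deg[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  class(out) <- c("hub_ranking", class(out))
  out
}

#' Density of the induced subgraph of the top-i hubs, for growing i
#'
#' Traces how densely the highest-degree nodes interconnect: for each
#' i = 2..k_max, the edge density of the subgraph induced by the i
#' highest-ranked hubs. A plateau of high density over the first ranks
#' signals an interconnected hub club.
#'
#' @param g a `binary_network` or igraph object
#' @param ranking a `hub_ranking` from [rank_by_degree()] (computed from `g`
#'   when omitted)
#' @param k_max largest hub count to trace (defaults to all nodes)
#' @return data.frame (k, density)
#' @export
induced_density_curve <- function(g, ranking = NULL, k_max = NULL) {
  gr <- as_graph(g)
  if (is.null(ranking)) ranking <- rank_by_degree(gr)
  n <- igraph::vcount(gr)
  if (is.null(k_max)) k_max <- n
  if (k_max < 2L) stop("k_max must be at least 2", call. = FALSE)
  if (k_max > n) stop("k_max exceeds the number of nodes", call. = FALSE)
  dens <- vapply(2:k_max, function(i) {
    sub <- igraph::induced_subgraph(gr, ranking$node[seq_len(i)])
    net_density(sub)
  }, numeric(1))
  data.frame(k = 2:k_max, density = dens)
}

#' Detect assorted clubs of interconnected hubs
#'
#' An assorted club is a densely interconnected group among the
#' highest-degree nodes — a relaxation of a rich club whose internal density
#' need not be 1. Detection scans the degree ranking from the top: at each
#' hub count i the subgraph induced by the top-i hubs is examined, and the
#' club boundary k* is the largest i at which (a) every one of the top-i
#' hubs has at least one edge inside the induced subgraph, i.e. all current
#' hubs participate in components of size >= 2, and (b) the next hub (rank
#' i+1) has no edge to any of the top-i hubs. The scan is abandoned once two
#' or more of the leading hubs are simultaneously isolated in the induced
#' subgraph, at which point the interconnected-hub structure has broken
#' down. A transient single isolated hub is tolerated, since it may be the
#' seed of a second club whose remaining members rank just below it.
#'
#' Each connected component of size >= 2 of the top-k* induced subgraph is
#' reported as a club; components with internal density >= `min_density`
#' are flagged as confirmed, the rest are reported but unconfirmed.
#'
#' @param g a `binary_network` or igraph object with at least 2 nodes
#' @param ranking optional `hub_ranking` (recomputed when omitted)
#' @param min_density internal-density flag threshold (default 0.8)
#' @param k_fixed optional fixed hub count overriding the stopping rule,
#'   for reproducing a manually chosen boundary
#' @return list of class `assorted_clubs`: `clubs` (each a list with
#'   `members`, `internal_density`, `hub_rank_span`, `confirmed`), `k` (the
#'   chosen hub count, `NA` when no club exists), and `ranking`. Clubs are
#'   ordered by decreasing size, then by their best member rank.
#' @export
detect_assorted_clubs <- function(g, ranking = NULL, min_density = 0.8,
                                  k_fixed = NULL) {
  gr <- as_graph(g)
  n <- igraph::vcount(gr)
  if (n < 2L) stop("club detection needs at least 2 nodes", call. = FALSE)
  if (is.null(ranking)) ranking <- rank_by_degree(gr)
  adj <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = TRUE)) > 0
  ord <- match(ranking$node, rownames(adj))
  adj <- adj[ord, ord, drop = FALSE]

  k_star <- NA_integer_
  if (!is.null(k_fixed)) {
    if (k_fixed < 2L || k_fixed > n) {
      stop("k_fixed must lie between 2 and the node count", call. = FALSE)
    }
    k_star <- as.integer(k_fixed)
  } else {
    for (i in 2:n) {
      sub <- adj[seq_len(i), seq_len(i), drop = FALSE]
      n_isolated <- sum(rowSums(sub) == 0L)
      if (n_isolated >= 2L) break
      all_connected <- n_isolated == 0L
      next_detached <- i == n || !any(adj[i + 1L, seq_len(i)])
      if (all_connected && next_detached) k_star <- i
    }
  }

  if (is.na(k_star)) {
    return(structure(list(clubs = list(), k = NA_integer_, ranking = ranking),
                     class = "assorted_clubs"))
  }

  top <- ranking$node[seq_len(k_star)]
  sub <- igraph::induced_subgraph(gr, top)
  comp <- igraph::components(sub)
  clubs <- list()
  for (cid in seq_len(comp$no)) {
    members <- igraph::V(sub)$name[comp$membership == cid]
    if (length(members) < 2L) next
    dens <- net_density(igraph::induced_subgraph(sub, members))
    ranks <- ranking$rank[match(members, ranking$node)]
    clubs[[length(clubs) + 1L]] <- list(
      members = sort(members),
      internal_density = dens,
      hub_rank_span = c(min(ranks), max(ranks)),
      confirmed = dens >= min_density
    )
  }
  if (length(clubs) > 1L) {
    sizes <- vapply(clubs, function(cl) length(cl$members), integer(1))
    best <- vapply(clubs, function(cl) cl$hub_rank_span[1L], numeric(1))
    clubs <- clubs[order(-sizes, best)]
  }
  structure(list(clubs = clubs, k = k_star, ranking = ranking),
            class = "assorted_clubs")
}

#' @export
print.assorted_clubs <- function(x, ...) {
  if (length(x$clubs) == 0L) {
    cat("assorted_clubs: none detected\n")
    return(invisible(x))
  }
  cat(sprintf("assorted_clubs: %d club(s) among the top %d hubs\n",
              length(x$clubs), x$k))
  for (i in seq_along(x$clubs)) {
    cl <- x$clubs[[i]]
    cat(sprintf(
      "  club %d: %d members, density %.2f%s (ranks %d-%d)\n",
      i, length(cl$members), cl$internal_density,
      if (cl$confirmed) "" else " [unconfirmed]",
      cl$hub_rank_span[1L], cl$hub_rank_span[2L]
    ))
  }
  invisible(x)
}

#' Partition network nodes into club spheres of influence
#'
#' Labels every node by its relation to the detected clubs: club members
#' keep a `clubN` label; a non-club node adjacent to members of exactly one
#' club joins that club's sphere of influence (`sphereN`); nodes adjacent to
#' two or more clubs form the `intermediate` (transitory) zone; connected
#' nodes touching no club are `unassigned`; degree-0 nodes are `isolated`.
#'
#' @param g a `binary_network` or igraph object
#' @param clubs an `assorted_clubs` object, or a list of character vectors
#'   of member ids (pairwise disjoint)
#' @return data.frame (node, label) of class `sphere_partition`; labels are
#'   exhaustive and mutually exclusive over the node set
#' @export
partition_spheres <- function(g, clubs) {
  gr <- as_graph(g)
  if (inherits(clubs, "assorted_clubs")) {
    member_sets <- lapply(clubs$clubs, `[[`, "members")
  } else {
    member_sets <- lapply(clubs, as.character)
  }
  if (length(member_sets) == 0L) stop("no clubs supplied", call. = FALSE)
  all_members <- unlist(member_sets)
  if (anyDuplicated(all_members)) {
    stop("club member sets must be disjoint", call. = FALSE)
  }
  missing <- setdiff(all_members, igraph::V(gr)$name)
  if (length(missing) > 0L) {
    stop(sprintf("club members not in graph: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  nodes <- igraph::V(gr)$name
  deg <- igraph::degree(gr)
  adj <- igraph::as_adjacency_matrix(gr, sparse = TRUE)
  touches <- vapply(member_sets, function(members) {
    as.integer(Matrix::rowSums(adj[, members, drop = FALSE]) > 0)
  }, integer(length(nodes)))
  touches <- matrix(touches, nrow = length(nodes))
  n_clubs_touched <- rowSums(touches)

  label <- character(length(nodes))
  for (ci in seq_along(member_sets)) {
    label[nodes %in% member_sets[[ci]]] <- paste0("club", ci)
  }
  free <- !nzchar(label)
  for (ci in seq_along(member_sets)) {
    pick <- free & n_clubs_touched == 1L & touches[, ci] == 1L
    label[pick] <- paste0("sphere", ci)
  }
  label[free & n_clubs_touched >= 2L] <- "intermediate"
  label[free & n_clubs_touched == 0L & deg > 0L] <- "unassigned"
  label[free & deg == 0L] <- "isolated"

  out <- data.frame(node = nodes, label = label, stringsAsFactors = FALSE)
  class(out) <- c("sphere_partition", class(out))
  out
}
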