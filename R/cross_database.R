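#' Per-miRNA target coverage between two prediction databases
#'
#' For every miRNA present in both maps (after name canonicalization), the
#' meet/min overlap of its two target sets, quantifying how consistently
#' the two databases predict its targets. When the databases use different
#' gene-id namespaces an explicit mapping table must be supplied; matching
#' across namespaces by string equality would silently report zero overlap.
#'
#' @param tm_a,tm_b `target_map` objects
#' @param id_map optional data.frame with columns `from`, `to` translating
#'   `tm_b` gene ids into the namespace of `tm_a`; genes of `tm_b` without a
#'   mapping are dropped and counted in the report
#' @return data.frame of class `coverage_report`
#'   (mirna, coverage, size_a, size_b), sorted by decreasing coverage, with
#'   attributes `summary` (mean/min/max coverage), `n_unmapped_genes`, and
#'   `ambiguous_mirnas` (raw names excluded because several normalized to
#'   the same canonical id within one database)
#' @export
target_coverage <- function(tm_a, tm_b, id_map = NULL) {
  stopifnot(inherits(tm_a, "target_map"), inherits(tm_b, "target_map"))
  ca <- .canonical_entries(tm_a)
  cb <- .canonical_entries(tm_b)
  n_unmapped <- 0L
  if (!is.null(id_map)) {
    if (!all(c("from", "to") %in% names(id_map))) {
      stop("id_map needs columns 'from' and 'to'", call. = FALSE)
    }
    lut <- stats::setNames(as.character(id_map$to), as.character(id_map$from))
    cb$entries <- lapply(cb$entries, function(gs) {
      mapped <- lut[gs]
      n_unmapped <<- n_unmapped + sum(is.na(mapped))
      unique(mapped[!is.na(mapped)])
    })
  } else if (length(intersect(tm_a$universe, tm_b$universe)) == 0L) {
    stop(sprintf(
      paste0("no shared gene identifiers between '%s' and '%s'; ",
             "if the databases use different gene-id namespaces, ",
             "supply an id_map"),
      tm_a$source_label, tm_b$source_label
    ), call. = FALSE)
  }
  shared <- intersect(names(ca$entries), names(cb$entries))
  if (length(shared) == 0L) {
    stop("no shared miRNAs between the two databases after name normalization",
         call. = FALSE)
  }
  shared <- shared[vapply(cb$entries[shared], length, integer(1)) > 0L]
  cov <- vapply(shared, function(m) {
    meet_min(ca$entries[[m]], cb$entries[[m]])
  }, numeric(1))
  out <- data.frame(
    mirna = shared,
    coverage = cov,
    size_a = vapply(ca$entries[shared], length, integer(1)),
    size_b = vapply(cb$entries[shared], length, integer(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out <- out[order(-out$coverage, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- c(mean = mean(cov), min = min(cov), max = max(cov))
  attr(out, "n_unmapped_genes") <- n_unmapped
  attr(out, "ambiguous_mirnas") <- c(ca$ambiguous, cb$ambiguous)
  class(out) <- c("coverage_report", class(out))
  out
}

# canonicalize the miRNA names of a target map; raw names that collide
# after normalization are ambiguous many-to-one matches and are excluded
.canonical_entries <- function(tm) {
  canon <- normalize_mirna_name(names(tm$entries))
  dup <- canon[duplicated(canon)]
  ambiguous <- names(tm$entries)[canon %in% dup]
  keep <- !(canon %in% dup)
  entries <- tm$entries[keep]
  names(entries) <- canon[keep]
  list(entries = entries, ambiguous = ambiguous)
}

#' Hub recovery between two degree rankings
#'
#' How many of the top `k_a` hubs of one network reappear among the top
#' `k_b` hubs of another (after miRNA name canonicalization).
#'
#' @param ranking_a,ranking_b `hub_ranking` data.frames
#' @param k_a,k_b prefix sizes; values exceeding a ranking's length are
#'   clamped with a warning
#' @return list: `overlap` (count), `ids` (canonical ids recovered)
#' @export
hub_recovery <- function(ranking_a, ranking_b, k_a, k_b) {
  stopifnot(nrow(ranking_a) > 0L, nrow(ranking_b) > 0L)
  if (k_a > nrow(ranking_a)) {
    warning(sprintf("k_a = %d exceeds ranking length %d; clamped",
                    k_a, nrow(ranking_a)))
    k_a <- nrow(ranking_a)
  }
  if (k_b > nrow(ranking_b)) {
    warning(sprintf("k_b = %d exceeds ranking length %d; clamped",
                    k_b, nrow(ranking_b)))
    k_b <- nrow(ranking_b)
  }
  top_a <- normalize_mirna_name(ranking_a$node[seq_len(k_a)])
  top_b <- normalize_mirna_name(ranking_b$node[seq_len(k_b)])
  ids <- sort(intersect(top_a, top_b))
  list(overlap = length(ids), ids = ids)
}

#' Induced density of one node group in two networks
#'
#' Compares how densely a fixed group of miRNAs (e.g. the union of two
#' assorted clubs) interconnects in two networks built from different
#' prediction databases, with a per-pair edge presence/absence table.
#'
#' @param g_a,g_b `binary_network` or igraph objects (vertex names are
#'   canonicalized for matching)
#' @param members character vector of miRNA ids; members absent from either
#'   graph are reported and excluded
#' @return list: `density_a`, `density_b`, `pairs` (data.frame node_a,
#'   node_b, in_a, in_b, agree), `excluded` (members missing from a graph)
#' @export
club_density_profile <- function(g_a, g_b, members) {
  ga <- .canonical_graph(as_graph(g_a))
  gb <- .canonical_graph(as_graph(g_b))
  members <- unique(normalize_mirna_name(as.character(members)))
  present <- members[members %in% igraph::V(ga)$name &
                       members %in% igraph::V(gb)$name]
  excluded <- setdiff(members, present)
  if (length(present) < 2L) {
    stop("fewer than 2 club members are present in both networks",
         call. = FALSE)
  }
  sub_a <- igraph::induced_subgraph(ga, present)
  sub_b <- igraph::induced_subgraph(gb, present)
  cmb <- utils::combn(sort(present), 2L)
  in_a <- mapply(function(x, y) igraph::are_adjacent(sub_a, x, y),
                 cmb[1L, ], cmb[2L, ])
  in_b <- mapply(function(x, y) igraph::are_adjacent(sub_b, x, y),
                 cmb[1L, ], cmb[2L, ])
  list(
    density_a = net_density(sub_a),
    density_b = net_density(sub_b),
    pairs = data.frame(
      node_a = cmb[1L, ], node_b = cmb[2L, ],
      in_a = in_a, in_b = in_b, agree = in_a == in_b,
      stringsAsFactors = FALSE
    ),
    excluded = excluded
  )
}

.canonical_graph <- function(gr) {
  canon <- normalize_mirna_name(igraph::V(gr)$name)
  if (anyDuplicated(canon)) {
    dup <- unique(canon[duplicated(canon)])
    stop(sprintf("vertex names collide after normalization: %s",
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  igraph::set_vertex_attr(gr, "name", value = canon)
}

#' Write a coverage report as TSV
#' @param report a `coverage_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_coverage_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
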