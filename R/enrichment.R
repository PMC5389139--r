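#' Consensus target set of a miRNA group
#'
#' The genes targeted by at least a fixed fraction of a group of miRNAs.
#' The member threshold is `min_count = ceiling(fraction * |group|)`, so for
#' a club of 3 at fraction 0.5 a gene must be hit by at least 2 members, and
#' for a sphere of 129 at fraction 0.25 by at least 33.
#'
#' @param tm a `target_map`
#' @param group character vector of miRNA ids, all present in `tm`
#' @param fraction ratio in (0, 1]
#' @return list of class `consensus_set`: `group`, `fraction`, `min_count`,
#'   `genes` (sorted character vector). Higher fractions always yield
#'   subsets of lower-fraction consensus sets.
#' @export
consensus_targets <- function(tm, group, fraction) {
  stopifnot(inherits(tm, "target_map"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be a single value in (0, 1]", call. = FALSE)
  }
  group <- as.character(group)
  unknown <- setdiff(group, names(tm$entries))
  if (length(unknown) > 0L) {
    stop(sprintf("miRNAs not in target map: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  min_count <- as.integer(ceiling(fraction * length(group)))
  counts <- table(unlist(tm$entries[group], use.names = FALSE))
  genes <- sort(names(counts)[counts >= min_count])
  structure(
    list(group = group, fraction = fraction, min_count = min_count,
         genes = genes),
    class = "consensus_set"
  )
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf(
    "consensus_set: %d genes shared by >= %d of %d miRNAs (fraction %.2f)\n",
    length(x$genes), x$min_count, length(x$group), x$fraction
  ))
  invisible(x)
}

#' Broadly-targeted gene hubs
#'
#' Genes targeted by more miRNAs than a high quantile of the per-gene
#' targeting-count distribution. The cutoff is the empirical quantile
#' (default the 99th, continuous-interpolation estimator) and membership is
#' strict: a hub's miRNA count must exceed the cutoff.
#'
#' @param tm a `target_map`
#' @param quantile quantile level in (0, 1), default 0.99
#' @param type quantile estimator type passed to [stats::quantile()]
#'   (default 7, the continuous-interpolation default)
#' @return list of class `gene_hub_set`: `quantile`, `cutoff_count`, `genes`
#' @export
gene_hubs <- function(tm, quantile = 0.99, type = 7) {
  stopifnot(inherits(tm, "target_map"))
  counts <- summarize_targeting(tm)$gene_mirna_counts
  cutoff <- unname(stats::quantile(counts, probs = quantile, type = type))
  structure(
    list(
      quantile = quantile,
      cutoff_count = cutoff,
      genes = sort(names(counts)[counts > cutoff])
    ),
    class = "gene_hub_set"
  )
}

#' @export
print.gene_hub_set <- function(x, ...) {
  cat(sprintf("gene_hub_set: %d genes targeted by more than %s miRNAs (q=%.2f)\n",
              length(x$genes), format(x$cutoff_count), x$quantile))
  invisible(x)
}

#' One-sided Fisher overlap test between a study set and a hub set
#'
#' Tests whether a study gene set overlaps a hub set more than expected by
#' chance within a common gene universe, via the hypergeometric upper tail
#' (one-sided Fisher exact test for enrichment).
#'
#' @param study,hubs,universe character gene vectors; `study` and `hubs`
#'   must be subsets of `universe`
#' @return list: `overlap` (count), `expected` (overlap expected under
#'   independence), `odds_ratio` (sample odds ratio of the 2x2 table),
#'   `p_value` (one-sided enrichment p), `table` (the 2x2 contingency
#'   matrix)
#' @export
hub_overlap_test <- function(study, hubs, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  study <- unique(as.character(study))
  hubs <- unique(as.character(hubs))
  if (length(setdiff(study, universe)) > 0L) {
    stop("study set is not contained in the universe", call. = FALSE)
  }
  if (length(setdiff(hubs, universe)) > 0L) {
    stop("hub set is not contained in the universe", call. = FALSE)
  }
  k <- length(intersect(study, hubs))
  a <- k
  b <- length(study) - k
  c_ <- length(hubs) - k
  d <- length(universe) - a - b - c_
  p <- stats::phyper(k - 1, length(hubs), length(universe) - length(hubs),
                     length(study), lower.tail = FALSE)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("in_study", "not_study"),
                                c("in_hubs", "not_hubs")))
  list(
    overlap = k,
    expected = length(study) * length(hubs) / length(universe),
    odds_ratio = (a * d) / (b * c_),
    p_value = p,
    table = tab
  )
}

#' Gene -> GO term annotation table
#'
#' @param gene2term data.frame with columns `gene`, `term`
#' @param term_meta data.frame with columns `term`, `name`, `namespace`
#'   (namespace one of "BP", "MF", "CC")
#' @return object of class `annotation_table` with components `gene2term`
#'   (deduplicated) and `term_meta`
#' @export
annotation_table <- function(gene2term, term_meta) {
  stopifnot(is.data.frame(gene2term), is.data.frame(term_meta))
  if (!all(c("gene", "term") %in% names(gene2term))) {
    stop("gene2term needs columns 'gene' and 'term'", call. = FALSE)
  }
  if (!all(c("term", "name", "namespace") %in% names(term_meta))) {
    stop("term_meta needs columns 'term', 'name' and 'namespace'", call. = FALSE)
  }
  bad_ns <- setdiff(unique(term_meta$namespace), c("BP", "MF", "CC"))
  if (length(bad_ns) > 0L) {
    stop(sprintf("invalid GO namespaces: %s", paste(bad_ns, collapse = ", ")),
         call. = FALSE)
  }
  g2t <- unique(data.frame(
    gene = as.character(gene2term$gene),
    term = as.character(gene2term$term),
    stringsAsFactors = FALSE
  ))
  unknown <- setdiff(g2t$term, term_meta$term)
  if (length(unknown) > 0L) {
    stop(sprintf("terms without metadata: %s",
                 paste(utils::head(unknown, 5L), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(gene2term = g2t, term_meta = term_meta),
            class = "annotation_table")
}

#' Read an annotation table from TSV files
#' @param gene2term_path 2-column TSV (gene, term) with header
#' @param term_meta_path 3-column TSV (term, name, namespace) with header
#' @return an [annotation_table()]
#' @export
read_annotation_table <- function(gene2term_path, term_meta_path) {
  annotation_table(
    utils::read.delim(gene2term_path, stringsAsFactors = FALSE),
    utils::read.delim(term_meta_path, stringsAsFactors = FALSE)
  )
}

#' Classic Fisher GO enrichment of a study gene set
#'
#' Per-term one-sided Fisher exact test (hypergeometric upper tail) of a
#' study set against a gene universe, ignoring the ontology DAG structure
#' ("classic" algorithm: annotations are taken as already
#' ancestor-propagated). Benjamini-Hochberg adjustment is applied across
#' all tested terms within the namespace. For the BP namespace the default
#' size filter keeps only terms annotated to more than 10 and fewer than
#' 5,000 universe genes; filtered terms are excluded both from the output
#' and from the BH test count.
#'
#' The BH-significant flag (`p_bh < 0.05`) annotates rows but never
#' truncates the output: with a correlated GO term structure the BH
#' correction is conservative, so downstream interpretation should see the
#' full ranking.
#'
#' @param study character vector of study genes (subset of `universe`)
#' @param ann an `annotation_table`
#' @param universe character vector of background genes
#' @param namespace "BP", "MF" or "CC"
#' @param size_filter length-2 numeric `(min_annotated, max_annotated)`,
#'   exclusive bounds; `NULL` disables filtering. Default: `c(10, 5000)`
#'   for BP, none otherwise.
#' @return data.frame of class `enrichment_result`, sorted by increasing
#'   classic Fisher p: columns `term_id`, `term_name`, `annotated`,
#'   `significant`, `p_classic`, `p_bh`, `bh_significant`
#' @export
go_enrichment <- function(study, ann, universe,
                          namespace = c("BP", "MF", "CC"),
                          size_filter = if (namespace[1L] == "BP") c(10, 5000) else NULL) {
  namespace <- match.arg(namespace)
  stopifnot(inherits(ann, "annotation_table"))
  universe <- unique(as.character(universe))
  study <- unique(as.character(study))
  if (length(setdiff(study, universe)) > 0L) {
    stop("study set is not contained in the universe", call. = FALSE)
  }
  study <- intersect(study, universe)
  if (length(study) == 0L) {
    stop("empty study set after universe restriction", call. = FALSE)
  }
  ns_terms <- ann$term_meta$term[ann$term_meta$namespace == namespace]
  g2t <- ann$gene2term[ann$gene2term$term %in% ns_terms &
                         ann$gene2term$gene %in% universe, , drop = FALSE]
  if (nrow(g2t) == 0L) {
    return(.empty_enrichment())
  }
  term_genes <- split(g2t$gene, g2t$term)
  annotated <- vapply(term_genes, length, integer(1))
  significant <- vapply(term_genes, function(gs) {
    length(intersect(gs, study))
  }, integer(1))
  keep <- rep(TRUE, length(annotated))
  if (!is.null(size_filter)) {
    keep <- annotated > size_filter[1L] & annotated < size_filter[2L]
  }
  if (!any(keep)) return(.empty_enrichment())
  annotated <- annotated[keep]
  significant <- significant[keep]
  terms <- names(annotated)
  n_univ <- length(universe)
  n_study <- length(study)
  p <- stats::phyper(significant - 1L, annotated, n_univ - annotated,
                     n_study, lower.tail = FALSE)
  p_bh <- bh_adjust(p)
  meta <- ann$term_meta[match(terms, ann$term_meta$term), ]
  out <- data.frame(
    term_id = terms,
    term_name = meta$name,
    annotated = annotated,
    significant = significant,
    p_classic = p,
    p_bh = p_bh,
    bh_significant = p_bh < 0.05,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out <- out[order(out$p_classic, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

.empty_enrichment <- function() {
  out <- data.frame(
    term_id = character(0), term_name = character(0),
    annotated = integer(0), significant = integer(0),
    p_classic = numeric(0), p_bh = numeric(0),
    bh_significant = logical(0), stringsAsFactors = FALSE
  )
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Write an enrichment result as TSV
#'
#' Column layout: `GO.ID`, `Term`, `Annotated`, `Significant`,
#' `classicFisher`, `BH.pval`.
#'
#' @param res an `enrichment_result`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_enrichment <- function(res, path) {
  stopifnot(inherits(res, "enrichment_result"))
  out <- data.frame(
    GO.ID = res$term_id,
    Term = res$term_name,
    Annotated = res$annotated,
    Significant = res$significant,
    classicFisher = signif(res$p_classic, 3),
    BH.pval = signif(res$p_bh, 3),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, order-preserving with the input positions,
#'   each at most 1
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(is.na(pvals)) ||
      any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}
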