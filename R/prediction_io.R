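#' Canonical miRNA -> target-gene map
#'
#' A `target_map` is the substrate of every downstream analysis: a bipartite
#' mapping from each microRNA to the set of genes it is predicted to target,
#' together with optional per-pair binding-site counts and the gene universe
#' (the union of all target sets).
#'
#' @param pairs data.frame with columns `mirna`, `gene` and optionally
#'   `sites` (positive integer counts, default 1). Duplicate (mirna, gene)
#'   rows are collapsed to a single entry with their site counts summed.
#' @param source_label character tag recording where the predictions came
#'   from (file name, database name).
#'
#' @return An object of class `target_map` with components:
#'   \describe{
#'     \item{entries}{named list, miRNA -> sorted character vector of genes}
#'     \item{site_counts}{data.frame (mirna, gene, sites), one row per
#'       distinct pair}
#'     \item{universe}{sorted character vector of all genes}
#'     \item{source_label}{character}
#'   }
#' @export
target_map <- function(pairs, source_label = "unknown") {
  stopifnot(is.data.frame(pairs))
  if (!all(c("mirna", "gene") %in% names(pairs))) {
    stop("`pairs` must have columns 'mirna' and 'gene'", call. = FALSE)
  }
  if (nrow(pairs) == 0L) {
    stop("empty interaction table: no (mirna, gene) pairs", call. = FALSE)
  }
  mirna <- as.character(pairs$mirna)
  gene <- as.character(pairs$gene)
  if (any(!nzchar(mirna)) || any(!nzchar(gene))) {
    stop("mirna and gene identifiers must be non-empty strings", call. = FALSE)
  }
  sites <- if ("sites" %in% names(pairs)) as.integer(pairs$sites) else rep(1L, length(mirna))
  if (any(is.na(sites)) || any(sites < 1L)) {
    stop("site counts must be positive integers", call. = FALSE)
  }
  # collapse duplicate pairs, summing site counts
  key <- paste(mirna, gene, sep = "\r")
  agg <- rowsum(sites, key, reorder = TRUE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  mirna_u <- vapply(parts, `[[`, character(1), 1L)
  gene_u <- vapply(parts, `[[`, character(1), 2L)
  sc <- data.frame(
    mirna = mirna_u, gene = gene_u, sites = as.integer(agg[, 1L]),
    stringsAsFactors = FALSE
  )
  ord <- order(sc$mirna, sc$gene)
  sc <- sc[ord, , drop = FALSE]
  rownames(sc) <- NULL
  entries <- lapply(split(sc$gene, sc$mirna), sort)
  structure(
    list(
      entries = entries,
      site_counts = sc,
      universe = sort(unique(sc$gene)),
      source_label = source_label
    ),
    class = "target_map"
  )
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf(
    "target_map [%s]: %d miRNAs, %d genes, %d interactions\n",
    x$source_label, length(x$entries), length(x$universe), nrow(x$site_counts)
  ))
  invisible(x)
}

#' Number of miRNAs in a target map
#' @param tm a `target_map`
#' @return integer count
#' @export
n_mirnas <- function(tm) length(tm$entries)

# column mappings for the supported flat-file dialects; extra columns are
# ignored.  The 2009 DIANA-microT v3 layout is not standardized, so its
# mapping can be overridden via `col_map`.
.dialect_defaults <- list(
  generic_tsv = c(mirna = "mirna", gene = "gene", sites = "sites",
                  species = "species", score = "score"),
  diana_v3 = c(mirna = "mirna", gene = "ensembl_gene_id", sites = "sites",
               species = "species", score = "miTG_score"),
  targetscan_v62 = c(mirna = "miRNA", gene = "Gene.ID", sites = "sites",
                     species = "Species.ID", score = "score")
)

#' Read a miRNA target-prediction table into a target map
#'
#' Parses tab-separated prediction flat files. Three dialects are supported,
#' each a thin column mapping over the same record parser: `generic_tsv`
#' (columns `mirna`, `gene` and optionally `sites`, `species`, `score`),
#' `diana_v3` (Ensembl gene ids, miTG score column) and `targetscan_v62`
#' (the non-conserved site table: Entrez gene ids, numeric species taxon
#' column). Unknown extra columns are ignored.
#'
#' Records failing the species filter are dropped; duplicate (mirna, gene)
#' rows are collapsed with site counts summed. If a score column is present
#' only rows with score strictly greater than `score_min` (default 0, i.e.
#' any reported score) are kept; prediction scores are otherwise unused.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect one of `"generic_tsv"`, `"diana_v3"`, `"targetscan_v62"`.
#' @param species_filter species tag: a miRNA-name prefix such as `"hsa"`
#'   (matched against the miRNA id when no species column exists) or a value
#'   matched against the species column when one exists (e.g. `"9606"` for
#'   the TargetScan taxon column). `NULL` disables filtering.
#' @param col_map optional named character vector overriding the dialect's
#'   column mapping; names among `mirna`, `gene`, `sites`, `species`,
#'   `score`.
#' @param score_min rows with score <= `score_min` are dropped when a score
#'   column is present.
#' @return a [target_map()].
#' @export
read_prediction_table <- function(path,
                                  dialect = c("generic_tsv", "diana_v3", "targetscan_v62"),
                                  species_filter = "hsa",
                                  col_map = NULL,
                                  score_min = 0) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("cannot read prediction file '%s': no such file", path),
         call. = FALSE)
  }
  map <- .dialect_defaults[[dialect]]
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("mirna", "gene")
  have <- intersect(names(map), names(raw))
  got <- map[need] %in% names(raw)
  if (!all(got)) {
    stop(sprintf(
      "dialect '%s' expects columns %s; file has %s",
      dialect, paste(map[need][!got], collapse = ", "),
      paste(names(raw), collapse = ", ")
    ), call. = FALSE)
  }
  df <- data.frame(
    mirna = as.character(raw[[map[["mirna"]]]]),
    gene = as.character(raw[[map[["gene"]]]]),
    stringsAsFactors = FALSE
  )
  if (map[["sites"]] %in% names(raw)) df$sites <- as.integer(raw[[map[["sites"]]]])
  if (map[["score"]] %in% names(raw)) {
    keep <- !is.na(raw[[map[["score"]]]]) & raw[[map[["score"]]]] > score_min
    df <- df[keep, , drop = FALSE]
  }
  if (!is.null(species_filter)) {
    if (map[["species"]] %in% names(raw)) {
      sp <- as.character(raw[[map[["species"]]]])
      if (map[["score"]] %in% names(raw)) sp <- sp[keep]
      df <- df[sp == species_filter, , drop = FALSE]
    } else {
      pref <- paste0(tolower(species_filter), "-")
      df <- df[startsWith(tolower(df$mirna), pref), , drop = FALSE]
    }
  }
  if (nrow(df) == 0L) {
    stop(sprintf(
      "no records survive the species filter '%s' in '%s'",
      if (is.null(species_filter)) "<none>" else species_filter, path
    ), call. = FALSE)
  }
  target_map(df, source_label = basename(path))
}

#' Serialize a target map as a sorted 3-column TSV
#'
#' The canonical on-disk form: columns `mirna`, `gene`, `sites`, sorted by
#' miRNA then gene. Re-reading with [read_prediction_table()] under the
#' `generic_tsv` dialect round-trips the map.
#'
#' @param tm a `target_map`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_target_map <- function(tm, path) {
  stopifnot(inherits(tm, "target_map"))
  utils::write.table(tm$site_counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summarize targeting distributions of a target map
#'
#' @param tm a `target_map`
#' @return list with three named integer vectors:
#'   \describe{
#'     \item{mirna_gene_counts}{distinct target genes per miRNA}
#'     \item{mirna_site_counts}{total predicted binding sites per miRNA}
#'     \item{gene_mirna_counts}{number of miRNAs targeting each gene}
#'   }
#'   The totals of `mirna_gene_counts` and `gene_mirna_counts` are equal
#'   (both count the distinct bipartite edges).
#' @export
summarize_targeting <- function(tm) {
  stopifnot(inherits(tm, "target_map"))
  if (length(tm$entries) == 0L) stop("empty target_map", call. = FALSE)
  sc <- tm$site_counts
  gene_counts <- vapply(tm$entries, length, integer(1))
  site_counts <- vapply(split(sc$sites, sc$mirna), sum, integer(1))
  gm <- table(sc$gene)
  gene_mirna <- as.integer(gm)
  names(gene_mirna) <- names(gm)
  list(
    mirna_gene_counts = gene_counts,
    mirna_site_counts = site_counts[names(gene_counts)],
    gene_mirna_counts = gene_mirna
  )
}

#' Canonicalize a miRNA name
#'
#' Strips a species prefix (e.g. `"hsa-"`) when it precedes a `mir`/`let`
#' stem and lower-cases the result, so that names can be matched across
#' prediction databases. Idempotent.
#'
#' @param name character vector of miRNA names
#' @return character vector of canonical names
#' @examples
#' normalize_mirna_name(c("hsa-miR-661", "miR-661", "hsa-let-7a"))
#' @export
normalize_mirna_name <- function(name) {
  stopifnot(is.character(name), all(nzchar(name)))
  x <- tolower(name)
  sub("^[a-z]{3,4}-(?=(mir|let)-)", "", x, perl = TRUE)
}
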