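#' Assemble and validate a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one structure.
#' Defaults follow the reference analysis settings: binary threshold at
#' meet/min 0.5, consensus fractions 0.5 and 0.25, gene-hub quantile 0.99,
#' club density flag 0.8.
#'
#' @param input either a list `list(path=, dialect=, species_filter=)`
#'   pointing at a prediction flat file, or `"synthetic"` to generate data
#'   from `synthetic` settings
#' @param synthetic a [synthetic_config()] (used when `input` is
#'   `"synthetic"`)
#' @param tau binary meet/min threshold (default 0.5)
#' @param sweep_taus threshold grid for the property sweep (default 0 to 1
#'   step 0.01); `NULL` skips the sweep
#' @param min_density club internal-density flag threshold (default 0.8)
#' @param k_fixed optional fixed hub count for club detection
#' @param consensus_fractions fractions for consensus target sets
#'   (default `c(0.5, 0.25)`)
#' @param hub_quantile gene-hub quantile (default 0.99)
#' @param annotations optional list `list(gene2term=, term_meta=)` of TSV
#'   paths for GO enrichment
#' @param go_namespace GO namespace for enrichment (default "BP")
#' @param seed integer seed for every random component
#' @param out_dir output directory (created if absent)
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(input = "synthetic",
                            synthetic = synthetic_config(),
                            tau = 0.5,
                            sweep_taus = seq(0, 1, by = 0.01),
                            min_density = 0.8,
                            k_fixed = NULL,
                            consensus_fractions = c(0.5, 0.25),
                            hub_quantile = 0.99,
                            annotations = NULL,
                            go_namespace = "BP",
                            seed = 1L,
                            out_dir = tempfile("mirclubs_run_")) {
  cfg <- list(
    input = input, synthetic = synthetic, tau = tau, sweep_taus = sweep_taus,
    min_density = min_density, k_fixed = k_fixed,
    consensus_fractions = consensus_fractions, hub_quantile = hub_quantile,
    annotations = annotations, go_namespace = go_namespace,
    seed = as.integer(seed), out_dir = out_dir
  )
  if (is.list(input)) {
    if (is.null(input$path) || !file.exists(input$path)) {
      stop(sprintf("input prediction file '%s' does not exist",
                   if (is.null(input$path)) "<missing>" else input$path),
           call. = FALSE)
    }
  } else if (!identical(input, "synthetic")) {
    stop("input must be 'synthetic' or a list(path=, dialect=, species_filter=)",
         call. = FALSE)
  }
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]", call. = FALSE)
  if (any(consensus_fractions <= 0) || any(consensus_fractions > 1)) {
    stop("consensus fractions must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(annotations)) {
    for (p in unlist(annotations)) {
      if (!file.exists(p)) {
        stop(sprintf("annotation file '%s' does not exist", p), call. = FALSE)
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; the
#' `synthetic` block holds [synthetic_config()] fields.
#'
#' @param path YAML file path
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, as.list(y$synthetic %||% list()))
  args <- y[setdiff(names(y), "synthetic")]
  args$synthetic <- syn
  if (!is.null(args$sweep_taus)) args$sweep_taus <- as.numeric(args$sweep_taus)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full co-targeting network analysis
#'
#' Executes read (or simulate) -> weighted network -> threshold sweep ->
#' binary network -> graph metrics -> hub ranking -> assorted clubs ->
#' sphere partition -> consensus target sets -> gene hubs -> hub-overlap
#' tests (-> GO enrichment when annotations are configured), writing every
#' intermediate as TSV/GraphML under the configured output directory plus a
#' machine-readable JSON run report and a plain-text log of versions, seed
#' and parameters.
#'
#' @param cfg a `pipeline_config`
#' @return the run report (named list), invisibly; also written as
#'   `report.json`
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  log_lines <- c(
    sprintf("mirclubs %s | R %s | igraph %s",
            as.character(utils::packageVersion("mirclubs")),
            paste(R.version$major, R.version$minor, sep = "."),
            as.character(utils::packageVersion("igraph"))),
    sprintf("seed=%d tau=%.3f (edge kept iff meet/min >= tau) min_density=%.2f",
            cfg$seed, cfg$tau, cfg$min_density),
    sprintf("hub_quantile=%.3f (type-7 estimator, strict '>' at the cutoff)",
            cfg$hub_quantile),
    sprintf("consensus_fractions=%s (min_count = ceiling(fraction * group size))",
            paste(cfg$consensus_fractions, collapse = ",")),
    sprintf("degree ties broken lexicographically by miRNA id")
  )
  stage <- "input"
  report <- list(seed = cfg$seed, tau = cfg$tau)
  tryCatch({
    truth <- NULL
    if (identical(cfg$input, "synthetic")) {
      syn_cfg <- cfg$synthetic
      syn_cfg$seed <- cfg$seed
      sim <- generate_prediction_table(syn_cfg)
      tm <- sim$target_map
      truth <- sim$truth
      log_lines <- c(log_lines, "input: synthetic prediction table")
    } else {
      tm <- read_prediction_table(cfg$input$path,
                                  dialect = cfg$input$dialect %||% "generic_tsv",
                                  species_filter = cfg$input$species_filter %||% "hsa")
      log_lines <- c(log_lines, sprintf("input: %s", cfg$input$path))
    }
    write_target_map(tm, out("target_map.tsv"))
    report$n_mirnas <- length(tm$entries)
    report$n_genes <- length(tm$universe)

    stage <- "weighted_network"
    w <- build_weighted_network(tm)
    write_weighted_network(w, out("weighted_network.tsv"))
    report$n_weighted_pairs <- nrow(sim_pairs(w))

    stage <- "threshold_sweep"
    if (!is.null(cfg$sweep_taus)) {
      sweep <- threshold_sweep(w, cfg$sweep_taus)
      utils::write.table(sweep, out("sweep.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }

    stage <- "binary_network"
    bn <- threshold_network(w, cfg$tau)
    pm <- path_metrics(bn)
    cent <- node_centralities(bn)
    report$n_edges <- igraph::ecount(bn$graph)
    report$density <- net_density(bn)
    report$global_clustering <- global_clustering(bn)
    report$assortativity <- degree_assortativity(bn)
    report$diameter <- pm$diameter
    report$avg_path_length <- pm$avg_path_length
    report$n_isolated <- sum(cent$degree == 0L)

    stage <- "clubs"
    ranking <- rank_by_degree(bn)
    curve <- induced_density_curve(bn, ranking,
                                   k_max = min(50L, igraph::vcount(bn$graph)))
    utils::write.table(curve, out("induced_density_curve.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    clubs <- detect_assorted_clubs(bn, ranking, min_density = cfg$min_density,
                                   k_fixed = cfg$k_fixed)
    report$k_hubs <- clubs$k
    report$clubs <- lapply(clubs$clubs, function(cl) {
      list(members = cl$members, internal_density = cl$internal_density,
           confirmed = cl$confirmed)
    })

    stage <- "spheres"
    partition <- NULL
    if (length(clubs$clubs) > 0L) {
      partition <- partition_spheres(bn, clubs)
      merged <- merge(merge(partition, cent, by = "node"),
                      data.frame(node = ranking$node,
                                 club_id = .club_id_of(ranking$node, clubs)),
                      by = "node")
      utils::write.table(merged, out("spheres.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      report$sphere_sizes <- as.list(table(partition$label))
      export_graph(bn, attrs = partition, path = out("network.graphml"),
                   format = "graphml")
    } else {
      export_graph(bn, path = out("network.graphml"), format = "graphml")
    }

    stage <- "consensus"
    report$consensus <- list()
    for (ci in seq_along(clubs$clubs)) {
      for (fr in cfg$consensus_fractions) {
        cs <- consensus_targets(tm, clubs$clubs[[ci]]$members, fr)
        tag <- sprintf("club%d_f%02d", ci, round(100 * fr))
        utils::write.table(
          data.frame(gene = cs$genes), out(sprintf("consensus_%s.tsv", tag)),
          sep = "\t", quote = FALSE, row.names = FALSE
        )
        report$consensus[[tag]] <- length(cs$genes)
      }
    }

    stage <- "gene_hubs"
    hubs <- gene_hubs(tm, quantile = cfg$hub_quantile)
    utils::write.table(data.frame(gene = hubs$genes), out("gene_hubs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$gene_hub_cutoff <- hubs$cutoff_count
    report$n_gene_hubs <- length(hubs$genes)

    stage <- "hub_overlap"
    report$hub_overlap <- list()
    for (ci in seq_along(clubs$clubs)) {
      cs <- consensus_targets(tm, clubs$clubs[[ci]]$members, 1.0)
      if (length(cs$genes) == 0L) next
      ht <- hub_overlap_test(cs$genes, hubs$genes, tm$universe)
      report$hub_overlap[[sprintf("club%d", ci)]] <-
        list(overlap = ht$overlap, expected = ht$expected, p = ht$p_value)
    }

    stage <- "enrichment"
    if (!is.null(cfg$annotations) && length(clubs$clubs) > 0L) {
      ann <- read_annotation_table(cfg$annotations$gene2term,
                                   cfg$annotations$term_meta)
      for (ci in seq_along(clubs$clubs)) {
        cs <- consensus_targets(tm, clubs$clubs[[ci]]$members,
                                max(cfg$consensus_fractions))
        if (length(cs$genes) == 0L) next
        res <- go_enrichment(cs$genes, ann, tm$universe,
                             namespace = cfg$go_namespace)
        write_enrichment(res, out(sprintf("enrichment_club%d_%s.tsv",
                                          ci, cfg$go_namespace)))
        report$enrichment[[sprintf("club%d", ci)]] <-
          list(n_terms_tested = nrow(res),
               n_bh_significant = sum(res$bh_significant))
      }
    }

    if (!is.null(truth)) {
      report$truth <- list(
        club_memberships = truth$club_memberships,
        n_hub_genes_planted = length(truth$hub_genes),
        hub_recovery = if (length(truth$hub_genes) > 0L) {
          length(intersect(hubs$genes, truth$hub_genes)) / length(truth$hub_genes)
        } else NA
      )
    }
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, out("run.log"))
  invisible(report)
}

.club_id_of <- function(nodes, clubs) {
  id <- rep(NA_integer_, length(nodes))
  for (ci in seq_along(clubs$clubs)) {
    id[nodes %in% clubs$clubs[[ci]]$members] <- ci
  }
  id
}

#' Export a binary network with node attributes
#'
#' Writes the network as GraphML (lossless round trip of nodes, edges and
#' node attributes) or as an undirected edge-list TSV.
#'
#' @param g a `binary_network` or igraph object
#' @param attrs optional data.frame with a `node` column plus attribute
#'   columns; every id must be a graph node
#' @param path output file path
#' @param format `"graphml"` or `"edgelist_tsv"`
#' @return `path`, invisibly
#' @export
export_graph <- function(g, attrs = NULL, path,
                         format = c("graphml", "edgelist_tsv")) {
  format <- match.arg(format)
  gr <- as_graph(g)
  if (!is.null(attrs)) {
    attrs <- as.data.frame(attrs)
    if (!"node" %in% names(attrs)) {
      stop("attrs needs a 'node' column", call. = FALSE)
    }
    unknown <- setdiff(attrs$node, igraph::V(gr)$name)
    if (length(unknown) > 0L) {
      stop(sprintf("attribute ids that are not graph nodes: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    for (col in setdiff(names(attrs), "node")) {
      vals <- attrs[[col]][match(igraph::V(gr)$name, attrs$node)]
      gr <- igraph::set_vertex_attr(gr, col, value = vals)
    }
  }
  if (format == "graphml") {
    igraph::write_graph(gr, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(gr, names = TRUE)
    utils::write.table(
      data.frame(node_a = el[, 1L], node_b = el[, 2L]),
      path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' Re-import a GraphML export as a binary network
#' @param path GraphML file
#' @return a `binary_network` (threshold `NA`)
#' @export
import_graphml <- function(path) {
  gr <- igraph::read_graph(path, format = "graphml")
  binary_network(gr, threshold_used = NA_real_)
}
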