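#' Configuration for the synthetic prediction-table generator
#'
#' Describes a Bernoulli bipartite targeting model with planted structure:
#' a random background where every (miRNA, gene) pair is targeted
#' independently with `base_target_prob`; a set of miRNA clubs, each with a
#' dedicated gene pool that every member targets with `pool_prob` (planting
#' high pairwise meet/min within the club); and a set of hub genes that
#' every miRNA additionally targets with `hub_extra_prob` (planting
#' broadly-targeted genes). The defaults emulate, at desk scale, a
#' prediction database harbouring two interconnected hub clubs of 8 and 3
#' miRNAs over a diffuse targeting background.
#'
#' @param n_mirnas number of miRNAs (default 200)
#' @param n_genes number of genes (default 2000)
#' @param base_target_prob background targeting probability (default 0.05)
#' @param clubs list of club descriptors, each a list with `n_members`,
#'   `pool_size`, `pool_prob`; pools are disjoint gene blocks (default: two
#'   clubs of 8 and 3 members with 300-gene pools at probability 0.9)
#' @param n_hub_genes number of planted hub genes (default 20)
#' @param hub_extra_prob extra targeting probability of hub genes by every
#'   miRNA (default 0.6)
#' @param seed integer seed making the generator fully reproducible
#' @return validated list of class `synthetic_config`
#' @export
synthetic_config <- function(n_mirnas = 200L,
                             n_genes = 2000L,
                             base_target_prob = 0.05,
                             clubs = list(
                               list(n_members = 8L, pool_size = 300L, pool_prob = 0.9),
                               list(n_members = 3L, pool_size = 300L, pool_prob = 0.9)
                             ),
                             n_hub_genes = 20L,
                             hub_extra_prob = 0.6,
                             seed = 1L) {
  cfg <- list(
    n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
    base_target_prob = base_target_prob, clubs = clubs,
    n_hub_genes = as.integer(n_hub_genes), hub_extra_prob = hub_extra_prob,
    seed = as.integer(seed)
  )
  problems <- character(0)
  if (cfg$n_mirnas < 1L) problems <- c(problems, "n_mirnas must be >= 1")
  if (cfg$n_genes < 1L) problems <- c(problems, "n_genes must be >= 1")
  for (p in c("base_target_prob", "hub_extra_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      problems <- c(problems, sprintf("%s must lie in [0, 1]", p))
    }
  }
  n_members <- sum(vapply(clubs, function(cl) as.integer(cl$n_members), integer(1)))
  pool_total <- sum(vapply(clubs, function(cl) as.integer(cl$pool_size), integer(1)))
  for (cl in clubs) {
    if (cl$pool_prob < 0 || cl$pool_prob > 1) {
      problems <- c(problems, "club pool_prob must lie in [0, 1]")
    }
    if (cl$n_members < 1L) problems <- c(problems, "club n_members must be >= 1")
  }
  if (n_members > cfg$n_mirnas) {
    problems <- c(problems, "club member counts exceed n_mirnas")
  }
  if (pool_total + cfg$n_hub_genes > cfg$n_genes) {
    problems <- c(problems, "club pools plus hub genes exceed n_genes")
  }
  if (cfg$n_hub_genes < 0L) problems <- c(problems, "n_hub_genes must be >= 0")
  if (length(problems) > 0L) {
    stop(paste0("invalid synthetic_config:\n  - ",
                paste(problems, collapse = "\n  - ")), call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic prediction table with planted clubs and hub genes
#'
#' Draws a bipartite targeting table from the Bernoulli model described in
#' [synthetic_config()]. A (miRNA, gene) pair is targeted when any of the
#' applicable mechanisms fires (background, club pool, hub gene), i.e. with
#' probability `1 - (1-p_base)(1-p_pool)(1-p_hub)`. Output is byte-identical
#' under the same seed.
#'
#' Club members are the first miRNAs in id order; each club's pool is a
#' dedicated block of gene ids and the hub genes occupy a block of their
#' own, so the planted truth is disjoint by construction.
#'
#' @param cfg a `synthetic_config`
#' @return list: `target_map` (a [target_map()]) and `truth` (class
#'   `synthetic_truth`: `club_memberships` list of miRNA id vectors,
#'   `hub_genes` character vector)
#' @export
generate_prediction_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  mirnas <- sprintf("mir-%03d", seq_len(cfg$n_mirnas))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))

  prob <- matrix(cfg$base_target_prob, nrow = cfg$n_mirnas, ncol = cfg$n_genes)
  memberships <- list()
  mir_off <- 0L
  gene_off <- 0L
  for (cl in cfg$clubs) {
    mi <- mir_off + seq_len(cl$n_members)
    gi <- gene_off + seq_len(cl$pool_size)
    prob[mi, gi] <- 1 - (1 - prob[mi, gi]) * (1 - cl$pool_prob)
    memberships[[length(memberships) + 1L]] <- mirnas[mi]
    mir_off <- mir_off + cl$n_members
    gene_off <- gene_off + cl$pool_size
  }
  hub_genes <- character(0)
  if (cfg$n_hub_genes > 0L) {
    hi <- gene_off + seq_len(cfg$n_hub_genes)
    prob[, hi] <- 1 - (1 - prob[, hi]) * (1 - cfg$hub_extra_prob)
    hub_genes <- genes[hi]
  }

  hit <- with_seed(cfg$seed, {
    matrix(stats::runif(length(prob)) < prob,
           nrow = cfg$n_mirnas, ncol = cfg$n_genes)
  })
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("synthetic generator produced no interactions; increase the targeting probabilities",
         call. = FALSE)
  }
  tm <- target_map(
    data.frame(mirna = mirnas[idx[, 1L]], gene = genes[idx[, 2L]],
               stringsAsFactors = FALSE),
    source_label = sprintf("synthetic(seed=%d)", cfg$seed)
  )
  truth <- structure(
    list(club_memberships = memberships, hub_genes = hub_genes,
         de_features = NULL),
    class = "synthetic_truth"
  )
  list(target_map = tm, truth = truth)
}

#' Generate a synthetic expression matrix with planted group shifts
#'
#' Control samples are i.i.d. normal around `baseline` with standard
#' deviation `noise_sd`; case samples add a planted per-feature shift.
#' Values are on log2 scale by construction, so [group_logfc()] estimates
#' the planted shifts directly.
#'
#' @param n_features number of features (miRNAs)
#' @param n_per_group samples per group (the same for case and control)
#' @param shifts numeric vector of planted log2 shifts: either length
#'   `n_features` or a named vector over a subset of feature ids
#'   (`mir-001` style); unnamed features shift by 0
#' @param noise_sd noise standard deviation (> 0)
#' @param baseline baseline log2 expression (default 7)
#' @param seed integer seed
#' @return list: `matrix` (features x samples, colnames `ctrl_*`/`case_*`),
#'   `groups` (character vector per column), `truth` (class
#'   `synthetic_truth` with `de_features` = the full planted shift vector)
#' @export
generate_expression_matrix <- function(n_features, n_per_group, shifts = 0,
                                       noise_sd = 0.3, baseline = 7,
                                       seed = 1L) {
  n_features <- as.integer(n_features)
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  if (n_features < 1L) stop("n_features must be >= 1", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("noise_sd must be > 0", call. = FALSE)
  }
  features <- sprintf("mir-%03d", seq_len(n_features))
  shift_vec <- rep(0, n_features)
  names(shift_vec) <- features
  if (!is.null(names(shifts)) && any(nzchar(names(shifts)))) {
    unknown <- setdiff(names(shifts), features)
    if (length(unknown) > 0L) {
      stop(sprintf("shift features not generated: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    shift_vec[names(shifts)] <- shifts
  } else {
    shift_vec[] <- rep_len(shifts, n_features)
  }
  m <- with_seed(seed, {
    ctrl <- matrix(stats::rnorm(n_features * n_per_group, baseline, noise_sd),
                   nrow = n_features)
    case <- matrix(stats::rnorm(n_features * n_per_group, baseline, noise_sd),
                   nrow = n_features) + shift_vec
    cbind(ctrl, case)
  })
  rownames(m) <- features
  colnames(m) <- c(sprintf("ctrl_%02d", seq_len(n_per_group)),
                   sprintf("case_%02d", seq_len(n_per_group)))
  groups <- rep(c("control", "case"), each = n_per_group)
  truth <- structure(
    list(club_memberships = NULL, hub_genes = NULL, de_features = shift_vec),
    class = "synthetic_truth"
  )
  list(matrix = m, groups = groups, truth = truth)
}
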