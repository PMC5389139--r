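#' Shift an expression matrix to a minimum of 1 and log2-transform
#'
#' Raw expression matrices containing values below 1 (including negative
#' intensities) are adjusted by adding a single constant so that the
#' minimum observed value equals 1, then log2-transformed. Matrices whose
#' minimum is already at least 1 are log2-transformed directly.
#'
#' @param m numeric matrix (features x samples)
#' @return transformed matrix of the same shape
#' @export
log2_shift <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0L) stop("empty expression matrix", call. = FALSE)
  if (any(!is.finite(m))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  lo <- min(m)
  if (lo < 1) m <- m + (1 - lo)
  log2(m)
}

#' Quantile normalization of an expression matrix
#'
#' Forces all sample columns to share the same empirical distribution: each
#' column's sorted values are replaced by the across-column mean of the
#' order statistics, preserving within-column ranks; ties receive the mean
#' of their assigned values. Idempotent on tie-free matrices.
#'
#' @param m numeric matrix (features x samples) with at least 2 columns
#' @return normalized matrix of the same shape and dimnames
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) {
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Overlay scaling of node expression values
#'
#' Maps per-feature expression values to \[0, 1\] for coloring network
#' nodes on a white-to-red gradient: the median expression anchors 0
#' (white) and the maximum anchors 1, so only features expressed above the
#' dataset median are colored. Values at or below the median clamp to 0;
#' when all values are equal everything maps to 0.
#'
#' @param values named numeric vector (feature -> expression); non-finite
#'   entries propagate as `NA`
#' @return object of class `overlay_scale`: list with `scale` (named vector
#'   in \[0, 1\]), `median`, `max`
#' @export
overlay_scale <- function(values) {
  v <- as.numeric(values)
  names(v) <- names(values)
  finite <- is.finite(v)
  if (!any(finite)) stop("no finite expression values", call. = FALSE)
  med <- stats::median(v[finite])
  mx <- max(v[finite])
  scl <- rep(NA_real_, length(v))
  if (mx > med) {
    scl[finite] <- pmax(0, (v[finite] - med) / (mx - med))
  } else {
    scl[finite] <- 0
  }
  names(scl) <- names(v)
  structure(list(scale = scl, median = med, max = mx),
            class = "overlay_scale")
}

#' Group log-fold-change on a log-scale expression matrix
#'
#' Per feature, the mean over case samples minus the mean over control
#' samples. The matrix is assumed to be on log2 scale already (see
#' [log2_shift()] and [quantile_normalize()]), so the difference is a log2
#' fold change.
#'
#' @param m numeric matrix (features x samples), log2 scale
#' @param groups character vector of group labels, one per column of `m`
#' @param case,control labels present in `groups`
#' @return named numeric vector, one log2 fold change per feature
#' @export
group_logfc <- function(m, groups, case, control) {
  m <- as.matrix(m)
  if (length(groups) != ncol(m)) {
    stop("`groups` must have one label per sample column", call. = FALSE)
  }
  for (lab in c(case, control)) {
    if (!lab %in% groups) {
      stop(sprintf("group label '%s' not present among samples", lab),
           call. = FALSE)
    }
  }
  rowMeans(m[, groups == case, drop = FALSE]) -
    rowMeans(m[, groups == control, drop = FALSE])
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and feature ids in the first column.
#'
#' @param path TSV path
#' @return numeric matrix with feature rownames and sample colnames
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix with rownames and colnames
#' @param path output path
#' @return `path`, invisibly
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample -> group assignment table
#' @param path 2-column TSV (sample, group) with header
#' @return named character vector sample -> group
#' @export
read_sample_groups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
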