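#' Filter low-expression genes and cells
#'
#' Genes detected (count > 0) in fewer than `min_cells_frac * N` cells are
#' removed first; cells expressing fewer than `min_genes_per_cell` of the
#' surviving genes are removed second. Survivor order is preserved.
#'
#' @param m an [expression_matrix()] with `space = "raw_counts"`.
#' @param min_cells_frac minimum fraction of cells a gene must be detected in.
#' @param min_genes_per_cell minimum number of detected genes per cell.
#' @return The filtered [expression_matrix()].
#' @export
filter_low_expression <- function(m, min_cells_frac = 0.01,
                                  min_genes_per_cell = 200) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$space != "raw_counts")
    stop("filter_low_expression expects raw counts, got ", m$space)
  n <- nrow(m$values)
  detected_cells <- colSums(m$values > 0)
  # a gene never detected is removed regardless of the threshold
  keep_genes <- detected_cells > 0 & detected_cells >= min_cells_frac * n
  if (!any(keep_genes))
    stop("all genes removed; lower min_cells_frac (", min_cells_frac, ")")
  v <- m$values[, keep_genes, drop = FALSE]
  keep_cells <- rowSums(v > 0) >= min_genes_per_cell
  if (!any(keep_cells))
    stop("all cells removed; lower min_genes_per_cell (",
         min_genes_per_cell, ")")
  expression_matrix(v[keep_cells, , drop = FALSE], space = "raw_counts")
}

#' Library-size log-normalization
#'
#' Replaces each count x by `log(1 + scale_factor * x / libsize)` with the
#' per-cell library size (total counts). Zeros map to zeros.
#'
#' @param m an [expression_matrix()] with `space = "raw_counts"`.
#' @param scale_factor scale constant applied after library-size division
#'   (default 10,000).
#' @return An [expression_matrix()] with `space = "log_normalized"`.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$space != "raw_counts")
    stop("log_normalize expects raw counts, got ", m$space)
  lib <- rowSums(m$values)
  if (any(lib == 0))
    stop("cell(s) with zero library size: ",
         paste(m$cell_ids[lib == 0], collapse = ", "))
  v <- log1p(scale_factor * m$values / lib)
  expression_matrix(v, space = "log_normalized")
}

#' Select the most variable genes
#'
#' Genes are ranked by per-gene standard deviation of the log-normalized
#' values (descending, ties broken by original gene order) and the top
#' `min(n_top, G)` are kept, in rank order.
#'
#' @param m an [expression_matrix()] with `space = "log_normalized"` (set
#'   `check_space = FALSE` to rank raw counts instead).
#' @param n_top number of genes to keep (default 2000).
#' @param check_space require log-normalized input.
#' @return The reduced [expression_matrix()].
#' @export
select_top_variance_genes <- function(m, n_top = 2000, check_space = TRUE) {
  stopifnot(inherits(m, "expression_matrix"))
  if (check_space && m$space != "log_normalized")
    stop("select_top_variance_genes expects log-normalized input, got ",
         m$space)
  g <- ncol(m$values)
  sds <- apply(m$values, 2, stats::sd)
  ord <- order(-sds, seq_len(g))      # stable: ties keep file order
  keep <- ord[seq_len(min(n_top, g))]
  expression_matrix(m$values[, keep, drop = FALSE], space = m$space)
}
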