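#' Expression matrix container
#'
#' A light S3 container for a cells x genes expression matrix. `values` is a
#' dense base matrix with cells as rows; `space` records whether entries are
#' raw counts or log-normalized values.
#'
#' @param values numeric matrix, N cells x G genes.
#' @param cell_ids character vector of length N, unique.
#' @param gene_ids character vector of length G, unique.
#' @param space `"raw_counts"` or `"log_normalized"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              space = c("raw_counts", "log_normalized")) {
  space <- match.arg(space)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length (", length(cell_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length (", length(gene_ids), ") != number of columns (",
         ncol(values), ")")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ", paste(unique(cell_ids[duplicated(cell_ids)]),
                                       collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]),
                                       collapse = ", "))
  if (anyNA(values)) stop("expression values contain NA")
  if (space == "raw_counts" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative entry at cell '", cell_ids[bad[1]], "', gene '",
         gene_ids[bad[2]], "' not allowed for raw counts")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 space = space),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " cells x ", ncol(x$values),
      " genes [", x$space, "], ",
      sprintf("%.1f%% zeros\n", 100 * mean(x$values == 0)), sep = "")
  invisible(x)
}

#' Load an expression matrix from CSV/TSV/MatrixMarket
#'
#' CSV/TSV files must have a header row and ids in the first column.
#' MatrixMarket input requires sidecar text files with one row name and one
#' column name per line.
#'
#' @param path path to the matrix file.
#' @param fmt file format, one of `"csv"`, `"tsv"`, `"mtx"`.
#' @param orientation `"cells_by_genes"` (rows are cells) or
#'   `"genes_by_cells"` (transposed on load).
#' @param row_names,col_names for `fmt = "mtx"`: paths to the sidecar name
#'   files for the stored rows and columns.
#' @return An [expression_matrix()] in cells x genes orientation with
#'   `space = "raw_counts"`.
#' @export
load_expression <- function(path, fmt = c("csv", "tsv", "mtx"),
                            orientation = c("cells_by_genes", "genes_by_cells"),
                            row_names = NULL, col_names = NULL) {
  fmt <- match.arg(fmt)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt %in% c("csv", "tsv")) {
    sep <- if (fmt == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                        check.names = FALSE, comment.char = ""),
      error = function(e) stop("failed to parse ", fmt, " file '", path,
                               "': ", conditionMessage(e)))
    m <- as.matrix(df)
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))),
                   arr.ind = TRUE)
      stop("non-numeric entry in '", path, "' at data row ", bad[1, 1],
           ", column ", bad[1, 2])
    }
  } else {
    m <- tryCatch(as.matrix(Matrix::readMM(path)),
                  error = function(e) stop("failed to parse MTX file '", path,
                                           "': ", conditionMessage(e)))
    if (is.null(row_names) || is.null(col_names))
      stop("MTX input requires 'row_names' and 'col_names' sidecar files")
    rownames(m) <- readLines(row_names)
    colnames(m) <- readLines(col_names)
  }
  if (orientation == "genes_by_cells") m <- t(m)
  expression_matrix(m, space = "raw_counts")
}

#' Write an expression matrix to CSV/TSV/MatrixMarket
#'
#' @param m an [expression_matrix()].
#' @param path output path. For `fmt = "mtx"` the sidecar name files are
#'   written next to it as `<path>.rownames` and `<path>.colnames`.
#' @param fmt output format.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, fmt = c("csv", "tsv", "mtx")) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(m, "expression_matrix"))
  if (fmt %in% c("csv", "tsv")) {
    sep <- if (fmt == "csv") "," else "\t"
    df <- data.frame(id = m$cell_ids, m$values, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    writeLines(m$cell_ids, paste0(path, ".rownames"))
    writeLines(m$gene_ids, paste0(path, ".colnames"))
  }
  invisible(path)
}
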