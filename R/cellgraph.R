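#' Cell graph construction and normalization
#'
#' Cells are nodes; edges come from a KNN query in an embedding space,
#' OR-symmetrized and unweighted. The graph can be pruned per node by an
#' edge-length quantile cut and normalized for graph convolutions.
#'
#' @name cellgraph
NULL

new_cell_graph <- function(adjacency, pruned = FALSE) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (any(adjacency < 0)) stop("adjacency must be nonnegative")
  structure(list(adjacency = adjacency, pruned = pruned,
                 n_cells = nrow(adjacency)),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat("<cell_graph> ", x$n_cells, " cells, ", sum(x$adjacency > 0) / 2,
      " edges", if (x$pruned) " (pruned)", "\n", sep = "")
  invisible(x)
}

#' Degree matrix of a cell graph
#' @param g a `cell_graph`.
#' @return Diagonal matrix of row sums of the adjacency.
#' @export
graph_degree <- function(g) diag(rowSums(g$adjacency), g$n_cells)

#' Build a KNN cell graph from an embedding
#'
#' Edge (i, j) is present iff j is among the k nearest Euclidean neighbors
#' of i or vice versa (OR-symmetrization); edges are unweighted and
#' self-edges are excluded.
#'
#' @param embedding N x d numeric matrix.
#' @param k neighbor count, `k < N`.
#' @return A `cell_graph`.
#' @export
build_knn_graph <- function(embedding, k) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (",
                   n, ")")
  if (k < 1) stop("k must be >= 1")
  d <- as.matrix(stats::dist(embedding))
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    nn <- order(di)[seq_len(k)]   # stable: ties resolved by index
    a[i, nn] <- 1
  }
  a <- pmax(a, t(a))
  new_cell_graph(a, pruned = FALSE)
}

#' Prune noisy edges by per-node length quantile
#'
#' For each node, incident edges longer than the given quantile of that
#' node's incident edge lengths are flagged; an edge is removed if either
#' endpoint flags it (symmetrized removal). A node that would lose all
#' edges retains its single shortest original edge.
#'
#' @param g a `cell_graph` built from `embedding`.
#' @param embedding the N x d embedding the graph was built from.
#' @param quantile fraction in (0, 1]; edges with length above this
#'   per-node quantile are removed (default 0.9).
#' @return A pruned `cell_graph`.
#' @export
prune_graph <- function(g, embedding, quantile = 0.9) {
  stopifnot(inherits(g, "cell_graph"))
  n <- g$n_cells
  d <- as.matrix(stats::dist(as.matrix(embedding)))
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- which(g$adjacency[i, ] > 0)
    if (!length(nb)) next
    thr <- stats::quantile(d[i, nb], probs = quantile, names = FALSE)
    keep[i, nb[d[i, nb] <= thr]] <- TRUE
  }
  keep <- keep & t(keep)
  a <- g$adjacency * keep
  # connectivity guard: re-attach isolated nodes via their shortest edge
  for (i in which(rowSums(a) == 0)) {
    nb <- which(g$adjacency[i, ] > 0)
    if (!length(nb)) next
    j <- nb[which.min(d[i, nb])]
    a[i, j] <- a[j, i] <- g$adjacency[i, j]
  }
  new_cell_graph(a, pruned = TRUE)
}

new_normalized_adjacency <- function(matrix, scheme) {
  structure(list(matrix = matrix, scheme = scheme),
            class = "normalized_adjacency")
}

#' @export
print.normalized_adjacency <- function(x, ...) {
  cat("<normalized_adjacency> ", nrow(x$matrix), " cells, scheme = ",
      x$scheme, "\n", sep = "")
  invisible(x)
}

#' Symmetric GCN normalization with self-loops
#'
#' Returns `D^(-1/2) (A + I) D^(-1/2)` where D is the degree matrix of
#' `A + I`. Self-loops guarantee every node has positive degree; the result
#' is symmetric with spectral radius at most 1.
#'
#' @param g a `cell_graph` (or plain symmetric adjacency matrix).
#' @return A `normalized_adjacency` with `scheme = "symmetric"`.
#' @export
normalize_adjacency <- function(g) {
  a <- if (inherits(g, "cell_graph")) g$adjacency else as.matrix(g)
  a1 <- a + diag(nrow(a))
  dinv <- 1 / sqrt(rowSums(a1))
  new_normalized_adjacency(a1 * outer(dinv, dinv), "symmetric")
}

#' One step of the adjacency iteration
#'
#' Mixes the (normalized) pruned reference graph L0 with the row-normalized
#' current adjacency: `mix * L0 + (1 - mix) * RowNorm(A)`. A zero row of A
#' is replaced by the uniform distribution over that row's L0 neighbors.
#'
#' @param L0 reference matrix (a `normalized_adjacency` or plain matrix).
#' @param A current adjacency (a `cell_graph` or plain matrix).
#' @param mix mixing weight mu in `[0, 1]` (default 0.5).
#' @return A `normalized_adjacency` with `scheme = "iterative_mix"`.
#' @export
update_adjacency_iteration <- function(L0, A, mix = 0.5) {
  stopifnot(mix >= 0, mix <= 1)
  l0 <- if (inherits(L0, "normalized_adjacency")) L0$matrix else as.matrix(L0)
  a <- if (inherits(A, "cell_graph")) A$adjacency else as.matrix(A)
  if (!all(dim(l0) == dim(a))) stop("L0 and A shapes differ")
  rs <- rowSums(a)
  rn <- a / ifelse(rs == 0, 1, rs)
  zero_rows <- which(rs == 0)
  if (length(zero_rows)) {
    message("update_adjacency_iteration: ", length(zero_rows),
            " zero row(s) in A replaced by uniform over L0 neighbors")
    for (i in zero_rows) {
      nb <- which(l0[i, ] > 0)
      if (length(nb)) rn[i, nb] <- 1 / length(nb)
    }
  }
  new_normalized_adjacency(mix * l0 + (1 - mix) * rn, "iterative_mix")
}

#' Relative Frobenius change between two adjacency matrices
#' @param current,previous matrices (or `normalized_adjacency` objects).
#' @return `||current - previous||_F / ||previous||_F`.
#' @export
adjacency_delta <- function(current, previous) {
  c0 <- if (inherits(current, "normalized_adjacency")) current$matrix else current
  p0 <- if (inherits(previous, "normalized_adjacency")) previous$matrix else previous
  sqrt(sum((c0 - p0)^2)) / sqrt(sum(p0^2))
}

#' Export a cell graph as an edge-list data frame
#' @param g a `cell_graph`.
#' @param cell_ids optional node names.
#' @return data.frame (cell_i, cell_j, weight), upper-triangle edges only.
#' @export
graph_edge_list <- function(g, cell_ids = NULL) {
  idx <- which(upper.tri(g$adjacency) & g$adjacency > 0, arr.ind = TRUE)
  ids <- cell_ids %||% as.character(seq_len(g$n_cells))
  data.frame(cell_i = ids[idx[, 1]], cell_j = ids[idx[, 2]],
             weight = g$adjacency[idx])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
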