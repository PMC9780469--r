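#' Per-cluster autoencoders
#'
#' One autoencoder per cell type, trained on that cluster's rows of the
#' feature-AE reconstruction; the reconstructed blocks are reassembled in
#' the original cell order. Clusters smaller than `min_cluster_size` cannot
#' train a network and are passed through unchanged (logged).
#'
#' @param Xhat a `reconstructed_matrix` (or plain matrix) from the feature
#'   autoencoder.
#' @param labels a `cluster_assignment` (or 0-based integer vector).
#' @param trs a `trs_matrix` or NULL; rows are subset per cluster.
#' @param dims,lr,epochs,seed,alpha,trs_mode as in [train_feature_ae()];
#'   each cluster trains with seed `seed + cluster index`.
#' @param min_cluster_size smallest trainable cluster (default 10).
#' @param init optional named list (by cluster label) of parameter lists to
#'   warm-start each cluster's network from.
#' @return A `reconstructed_matrix` with `source = "cluster_ae"` carrying a
#'   `"params"` attribute (per-cluster parameter lists).
#' @export
train_cluster_ae <- function(Xhat, labels, trs = NULL, dims = c(512, 128),
                             lr = 1e-3, epochs = 500, seed = 1, alpha = 0.5,
                             trs_mode = "binary", min_cluster_size = 10,
                             init = NULL) {
  xm <- if (inherits(Xhat, "reconstructed_matrix")) Xhat$values else
    as.matrix(Xhat)
  lab <- if (inherits(labels, "cluster_assignment")) labels$labels else
    as.integer(labels)
  if (length(lab) != nrow(xm))
    stop("labels length (", length(lab), ") != number of cells (",
         nrow(xm), ")")
  tw <- if (alpha > 0) trs_weight(trs, trs_mode) else NULL
  out <- xm
  params <- list()
  for (cl in sort(unique(lab))) {
    idx <- which(lab == cl)
    if (length(idx) < min_cluster_size) {
      message("cluster ", cl, " has ", length(idx),
              " cells (< ", min_cluster_size, "); passed through untrained")
      next
    }
    w <- NULL
    if (!is.null(tw)) w <- (1 - alpha) + alpha * tw[idx, , drop = FALSE]
    fit <- train_dense_ae(xm[idx, , drop = FALSE], entry_weight = w,
                          dims = dims, lr = lr, epochs = epochs,
                          seed = seed + cl + 1L,
                          init = init[[as.character(cl)]])
    out[idx, ] <- fit$Xhat
    params[[as.character(cl)]] <- fit$params
  }
  res <- reconstructed_matrix(out, "cluster_ae")
  attr(res, "params") <- params
  res
}
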