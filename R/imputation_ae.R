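#' Imputation-autoencoder loss
#'
#' Five terms:
#' `(1 - alpha) * sum((X - Xhat)^2)` (plain reconstruction),
#' `alpha * sum((X - Xhat)^2 * TRS)` (regulation-state weighting),
#' `beta * sum(|w|)` (L1 on network weights),
#' `gamma1 * sum_ij A_ij * ||(X - Xhat)_i||^2` (cell-graph regularizer:
#' per-cell error weighted by graph degree), and
#' `gamma2 * sum_ij B_ij * ||(X - Xhat)_i||^2` (cell-type regularizer,
#' B_ij = 1 iff cells i and j share a type). An alternative pairwise
#' reading of the graph terms, `sum_ij A_ij * ||Xhat_i - Xhat_j||^2`, is
#' available via `graph_penalty = "pairwise"`.
#'
#' @param X,Xhat input and reconstruction (N x G).
#' @param trs_weight per-entry TRS weight matrix (NULL when `alpha = 0`).
#' @param A N x N cell-graph adjacency from the final iteration.
#' @param B N x N symmetric 0/1 same-cell-type matrix.
#' @param alpha,beta,gamma1,gamma2 regularization strengths (`beta` in
#'   `[0, 1]`).
#' @param weights_l1 scalar sum of absolute network weights.
#' @param graph_penalty `"weighted_error"` (default) or `"pairwise"`.
#' @return Scalar loss with a `"terms"` attribute giving the five components.
#' @export
imputation_loss <- function(X, Xhat, trs_weight = NULL, A, B, alpha = 0.5,
                            beta = 0.5, gamma1 = 0.1, gamma2 = 0.1,
                            weights_l1 = 0,
                            graph_penalty = c("weighted_error", "pairwise")) {
  graph_penalty <- match.arg(graph_penalty)
  if (!all(dim(X) == dim(Xhat))) stop("X and Xhat shapes differ")
  B <- as.matrix(B); A <- as.matrix(A)
  if (any(B != t(B)) || !all(B %in% c(0, 1)))
    stop("B must be a symmetric 0/1 matrix")
  sq <- (X - Xhat)^2
  t_mse <- (1 - alpha) * sum(sq)
  t_trs <- if (alpha > 0) {
    if (is.null(trs_weight)) stop("alpha > 0 requires trs_weight")
    alpha * sum(sq * trs_weight)
  } else 0
  row_sq <- rowSums(sq)
  if (graph_penalty == "weighted_error") {
    t_graph <- gamma1 * sum(rowSums(A) * row_sq)
    t_type <- gamma2 * sum(rowSums(B) * row_sq)
  } else {
    pair <- function(M, W) {
      d <- rowSums(M^2)
      sum(W * (outer(d, d, `+`) - 2 * tcrossprod(M)))
    }
    t_graph <- gamma1 * pair(Xhat, A)
    t_type <- gamma2 * pair(Xhat, B)
  }
  t_l1 <- beta * weights_l1
  out <- t_mse + t_trs + t_l1 + t_graph + t_type
  attr(out, "terms") <- c(mse = t_mse, trs = t_trs, l1 = t_l1,
                          graph = t_graph, cell_type = t_type)
  out
}

#' Train the imputation autoencoder
#'
#' Trains the feature-AE architecture on the pretreated expression matrix
#' under [imputation_loss()], using the final iteration's cell graph A and
#' same-type matrix B. The full reconstruction is returned; restricting the
#' replacement to observed zeros is a post-processing step
#' ([impute_zeros()]).
#'
#' @param X preprocessed [expression_matrix()] or plain matrix.
#' @param A final cell-graph adjacency (a `cell_graph` or matrix).
#' @param B same-type 0/1 matrix (or a `cluster_assignment`).
#' @param trs a `trs_matrix` or NULL.
#' @param dims,lr,epochs,seed training settings.
#' @param alpha,beta,gamma1,gamma2,trs_mode,graph_penalty loss settings.
#' @return List: `reconstructed` (a `reconstructed_matrix`), `loss_trace`,
#'   `weights_l1`, `params`.
#' @export
train_imputation_ae <- function(X, A, B, trs = NULL, dims = c(512, 128),
                                lr = 1e-3, epochs = 500, seed = 1,
                                alpha = 0.5, beta = 0.5, gamma1 = 0.1,
                                gamma2 = 0.1, trs_mode = "binary",
                                graph_penalty = c("weighted_error",
                                                  "pairwise")) {
  graph_penalty <- match.arg(graph_penalty)
  xm <- if (inherits(X, "expression_matrix")) X$values else as.matrix(X)
  a <- if (inherits(A, "cell_graph")) A$adjacency else as.matrix(A)
  b <- if (inherits(B, "cluster_assignment")) B$same_type_matrix else
    as.matrix(B)
  tw <- if (alpha > 0) trs_weight(trs, trs_mode) else NULL
  if (alpha > 0 && is.null(tw)) alpha <- 0
  w <- matrix(1 - alpha, nrow(xm), ncol(xm))
  if (!is.null(tw)) w <- w + alpha * tw
  lap <- NULL
  smooth <- 0
  if (graph_penalty == "weighted_error") {
    # degree-weighted per-cell error folds into the entry weights
    w <- w + gamma1 * rowSums(a) + gamma2 * rowSums(b)
  } else {
    # sum_ij W_ij ||Xhat_i - Xhat_j||^2 = 2 tr(Xhat' L Xhat), L = D - W
    lap <- gamma1 * (diag(rowSums(a)) - a) +
      gamma2 * (diag(rowSums(b)) - b)
    smooth <- 1
  }
  fit <- train_dense_ae(xm, entry_weight = w, dims = dims, lr = lr,
                        epochs = epochs, seed = seed, l1 = beta,
                        laplacian = lap, smooth_weight = smooth)
  rec <- fit$Xhat
  dimnames(rec) <- dimnames(xm)
  list(reconstructed = reconstructed_matrix(rec, "imputation_ae"),
       loss_trace = fit$loss_trace, weights_l1 = ae_weight_l1(fit$params),
       params = fit$params)
}

#' Replace observed zeros with reconstructed values
#'
#' @param X original matrix (or [expression_matrix()]).
#' @param Xhat reconstruction (or `reconstructed_matrix`).
#' @return Matrix equal to X except at original zeros, where the
#'   (nonnegativity-clamped) reconstructed values are inserted.
#' @export
impute_zeros <- function(X, Xhat) {
  xm <- if (inherits(X, "expression_matrix")) X$values else as.matrix(X)
  rm_ <- if (inherits(Xhat, "reconstructed_matrix")) Xhat$values else
    as.matrix(Xhat)
  out <- xm
  z <- xm == 0
  out[z] <- pmax(rm_[z], 0)
  out
}
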