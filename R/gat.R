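#' @name gat
#' @title Graph-attention convolutions and the graph autoencoder
#' @description
#' The graph autoencoder (GAE) encoder stacks two graph convolution layers
#' (output dims 32 and 16, ReLU). With `heads = 0` a layer is a plain GCN
#' propagation `relu(Atilde %*% H %*% W)`; with `heads = K >= 1` each head k
#' scores node pairs by the dot product `(W_k h_i) . (W_k h_j)`, normalizes
#' scores over each node's neighborhood with a softmax, aggregates the
#' transformed neighbor features with those attention coefficients, and the
#' K head outputs are averaged before the activation. The decoder
#' reconstructs the adjacency as `sigmoid(Z %*% t(Z))` and training
#' minimizes the mean binary cross-entropy against the self-loop-augmented
#' 0/1 adjacency. Gradients are derived by hand (softmax and Gram-matrix
#' chain rules) and optimized with Adam.
NULL

.sigmoid <- function(x) 1 / (1 + exp(-x))

.row_softmax_masked <- function(E, mask) {
  E[!mask] <- -Inf
  mx <- apply(E, 1, max)
  if (any(!is.finite(mx)))
    stop("node with empty neighborhood: add self-loops before attention")
  P <- exp(E - mx)
  P / rowSums(P)
}

#' Graph-attention coefficients
#'
#' Scores `e_ij = (W h_i) . (W h_j)` for masked pairs, softmax-normalized
#' over each node's neighborhood, so each row sums to 1 over its neighbors.
#'
#' @param H N x d node feature matrix.
#' @param W shared d x d' weight matrix.
#' @param mask N x N logical (or 0/1) neighborhood mask, symmetric with
#'   self-loops.
#' @param att_score `"dot"` (the plain inner product, the definition) or
#'   `"cosine"` (inner product of unit-normalized transforms; keeps the
#'   softmax in its responsive range on large-magnitude features — the
#'   training default of [train_gae()]).
#' @return N x N matrix of attention coefficients (zero outside the mask).
#' @export
attention_coefficients <- function(H, W, mask,
                                   att_score = c("dot", "cosine")) {
  att_score <- match.arg(att_score)
  M <- as.matrix(H) %*% W
  if (att_score == "cosine") {
    M <- M / (sqrt(rowSums(M^2)) + 1e-12)
  }
  .row_softmax_masked(tcrossprod(M), mask > 0)
}

gat_forward_one <- function(H, At, heads, W, att_score = "cosine") {
  if (heads == 0) {
    AH <- At %*% H
    S <- AH %*% W
    return(list(S = S, out = .relu(S), AH = AH, heads = 0L))
  }
  mask <- At > 0
  n <- nrow(H)
  S <- matrix(0, n, ncol(W[[1]]))
  Ms <- vector("list", heads)
  As <- vector("list", heads)
  Us <- vector("list", heads)
  rns <- vector("list", heads)
  for (k in seq_len(heads)) {
    M <- H %*% W[[k]]
    if (att_score == "cosine") {
      rn <- sqrt(rowSums(M^2)) + 1e-12
      U <- M / rn
    } else {
      rn <- rep(1, n)
      U <- M
    }
    A_att <- .row_softmax_masked(tcrossprod(U), mask)
    S <- S + (A_att %*% M) / heads
    Ms[[k]] <- M
    As[[k]] <- A_att
    Us[[k]] <- U
    rns[[k]] <- rn
  }
  list(S = S, out = .relu(S), M = Ms, A = As, U = Us, rn = rns,
       heads = as.integer(heads), att_score = att_score)
}

gat_backward_one <- function(H, At, W, cache, dOut) {
  GS <- dOut * (cache$S > 0)
  if (cache$heads == 0) {
    dW <- crossprod(cache$AH, GS)
    dH <- t(At) %*% GS %*% t(W)
    return(list(dW = dW, dH = dH))
  }
  heads <- cache$heads
  dW <- vector("list", heads)
  dH <- matrix(0, nrow(H), ncol(H))
  for (k in seq_len(heads)) {
    M <- cache$M[[k]]
    A_att <- cache$A[[k]]
    GSk <- GS / heads
    dA <- tcrossprod(GSk, M)                       # through aggregation
    dM <- crossprod(A_att, GSk)
    dE <- A_att * (dA - rowSums(A_att * dA))       # softmax rows
    G2 <- dE + t(dE)                               # through E = U U'
    if (cache$att_score == "cosine") {
      U <- cache$U[[k]]
      dU <- G2 %*% U
      dM <- dM + (dU - U * rowSums(U * dU)) / cache$rn[[k]]
    } else {
      dM <- dM + G2 %*% M
    }
    dW[[k]] <- crossprod(H, dM)
    dH <- dH + tcrossprod(dM, W[[k]])
  }
  list(dW = dW, dH = dH)
}

#' One graph convolution layer (GCN or multi-head GAT)
#'
#' @param H N x d_in input features.
#' @param Atilde a `normalized_adjacency` (or plain matrix). For
#'   `heads >= 1` only its nonzero pattern (which includes self-loops) is
#'   used as the attention mask; for `heads = 0` its values propagate.
#' @param heads number of attention heads K (0 disables attention).
#' @param W for `heads = 0` a single d_in x d_out matrix; otherwise a list
#'   of K per-head matrices.
#' @param activation activation function (default ReLU).
#' @param att_score attention score variant (see
#'   [attention_coefficients()]); default `"dot"`, the definition.
#' @return N x d_out output matrix.
#' @export
gat_layer <- function(H, Atilde, heads, W, activation = NULL,
                      att_score = c("dot", "cosine")) {
  att_score <- match.arg(att_score)
  At <- if (inherits(Atilde, "normalized_adjacency")) Atilde$matrix else
    as.matrix(Atilde)
  H <- as.matrix(H)
  if (heads >= 1 && !is.list(W)) W <- rep(list(W), heads)
  fw <- gat_forward_one(H, At, heads, W, att_score)
  if (is.null(activation)) fw$out else activation(fw$S)
}

#' Inner-product decoder of the graph autoencoder
#'
#' @param Z N x d embedding.
#' @return An `adjacency_reconstruction`: `values = sigmoid(Z %*% t(Z))`,
#'   symmetric with entries in (0, 1).
#' @export
gae_decode <- function(Z) {
  v <- .sigmoid(tcrossprod(as.matrix(Z)))
  structure(list(values = v), class = "adjacency_reconstruction")
}

#' Graph-autoencoder cross-entropy loss
#'
#' Mean binary cross-entropy over all N^2 entries between the 0/1 target
#' adjacency and the reconstruction; predictions are clamped to
#' `[eps, 1 - eps]`.
#'
#' @param A 0/1 target adjacency (self-loop-augmented).
#' @param Ahat an `adjacency_reconstruction` or matrix with entries in (0,1).
#' @param eps clamping constant.
#' @param pos_weight weight on the edge (a = 1) terms. The default 1 is the
#'   plain cross-entropy; training uses the class-balanced
#'   `#non-edges / #edges` so that a sparse graph cannot be "reconstructed"
#'   by predicting no edges at all.
#' @return Scalar loss (>= 0).
#' @export
gae_loss <- function(A, Ahat, eps = 1e-7, pos_weight = 1) {
  ah <- if (inherits(Ahat, "adjacency_reconstruction")) Ahat$values else
    as.matrix(Ahat)
  A <- as.matrix(A)
  if (!all(dim(A) == dim(ah))) stop("A and Ahat shapes differ")
  ah <- pmin(pmax(ah, eps), 1 - eps)
  -mean(pos_weight * A * log(ah) + (1 - A) * log(1 - ah))
}

#' Train the graph autoencoder
#'
#' Two graph convolution layers (d_in -> dims[1] -> dims[2], ReLU) are
#' trained by Adam to reconstruct the self-loop-augmented binarized
#' adjacency through the inner-product decoder under [gae_loss()].
#'
#' @param g a `cell_graph` (pruned) or a `normalized_adjacency` used for
#'   propagation; the reconstruction target is always the binarized
#'   adjacency pattern plus self-loops.
#' @param features N x d_in input features (e.g. the feature-AE
#'   reconstruction).
#' @param heads attention heads K (0 = plain GCN).
#' @param dims layer output sizes, default c(32, 16).
#' @param lr learning rate (default 0.001).
#' @param epochs training epochs (0 returns the initialization embedding).
#' @param seed RNG seed.
#' @param pos_weight weight on edge terms of the loss; the default
#'   `"balanced"` uses `#non-edges / #edges` (see [gae_loss()]), or pass a
#'   number.
#' @param init optional `weights` list (W1, W2) from a previous
#'   `graph_embedding` to warm-start from.
#' @param att_score attention score variant; the default `"cosine"`
#'   unit-normalizes the transformed features before the inner product.
#'   The plain `"dot"` score saturates the softmax on large-magnitude
#'   expression features (near-one-hot attention), which measurably
#'   degrades the embedding.
#' @return A `graph_embedding`: `Z` (N x dims[2]), `H1`, `weights`,
#'   `attention` (final per-head layer coefficients, NULL when heads = 0),
#'   `n_heads`, `loss_trace`, `Ahat`.
#' @export
train_gae <- function(g, features, heads = 3, dims = c(32, 16), lr = 1e-3,
                      epochs = 200, seed = 1, pos_weight = "balanced",
                      init = NULL, att_score = c("cosine", "dot")) {
  att_score <- match.arg(att_score)
  if (inherits(g, "cell_graph")) {
    At <- normalize_adjacency(g)$matrix
    target <- (g$adjacency > 0) * 1
  } else {
    At <- if (inherits(g, "normalized_adjacency")) g$matrix else as.matrix(g)
    target <- (At > 0) * 1
  }
  diag(target) <- 1
  if (identical(pos_weight, "balanced")) {
    pos_weight <- sum(target == 0) / sum(target == 1)
  }
  H0 <- as.matrix(features)
  n <- nrow(H0)
  if (nrow(At) != n) stop("features row count (", n,
                          ") != graph size (", nrow(At), ")")
  set.seed(seed)
  if (heads == 0) {
    W1 <- glorot_init(ncol(H0), dims[1])
    W2 <- glorot_init(dims[1], dims[2])
  } else {
    W1 <- lapply(seq_len(heads), function(k) glorot_init(ncol(H0), dims[1]))
    W2 <- lapply(seq_len(heads), function(k) glorot_init(dims[1], dims[2]))
  }
  shapes_ok <- function(a, b) {
    if (is.list(b)) {
      is.list(a) && length(a) == length(b) &&
        all(mapply(function(x, y) identical(dim(x), dim(y)), a, b))
    } else {
      !is.list(a) && identical(dim(a), dim(b))
    }
  }
  if (!is.null(init) && shapes_ok(init$W1, W1) && shapes_ok(init$W2, W2)) {
    W1 <- init$W1
    W2 <- init$W2
  }
  flat <- function(W1, W2) if (heads == 0) list(W1, W2) else c(W1, W2)
  st <- adam_init(flat(W1, W2))
  loss_trace <- numeric(epochs)
  fw1 <- gat_forward_one(H0, At, heads, W1, att_score)
  fw2 <- gat_forward_one(fw1$out, At, heads, W2, att_score)
  for (ep in seq_len(epochs)) {
    fw1 <- gat_forward_one(H0, At, heads, W1, att_score)
    fw2 <- gat_forward_one(fw1$out, At, heads, W2, att_score)
    Z <- fw2$out
    P <- .sigmoid(tcrossprod(Z))
    loss <- gae_loss(target, P, pos_weight = pos_weight)
    if (!is.finite(loss)) stop("non-finite GAE loss at epoch ", ep)
    loss_trace[ep] <- loss
    R <- ((((pos_weight - 1) * target + 1) * P) - pos_weight * target) / n^2
    dZ <- (R + t(R)) %*% Z
    bw2 <- gat_backward_one(fw1$out, At, W2, fw2, dZ)
    bw1 <- gat_backward_one(H0, At, W1, fw1, bw2$dH)
    grads <- if (heads == 0) list(bw1$dW, bw2$dW) else c(bw1$dW, bw2$dW)
    upd <- adam_step(flat(W1, W2), grads, st, lr = lr)
    st <- upd$state
    if (heads == 0) {
      W1 <- upd$params[[1]]; W2 <- upd$params[[2]]
    } else {
      W1 <- upd$params[seq_len(heads)]
      W2 <- upd$params[heads + seq_len(heads)]
    }
  }
  fw1 <- gat_forward_one(H0, At, heads, W1, att_score)
  fw2 <- gat_forward_one(fw1$out, At, heads, W2, att_score)
  structure(list(Z = fw2$out, H1 = fw1$out,
                 weights = list(W1 = W1, W2 = W2),
                 attention = if (heads == 0) NULL else fw2$A,
                 n_heads = as.integer(heads), loss_trace = loss_trace,
                 Ahat = .sigmoid(tcrossprod(fw2$out))),
            class = "graph_embedding")
}

#' @export
print.graph_embedding <- function(x, ...) {
  cat("<graph_embedding> ", nrow(x$Z), " cells x ", ncol(x$Z),
      " dims, heads = ", x$n_heads, "\n", sep = "")
  invisible(x)
}
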