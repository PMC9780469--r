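#' @name nn-core
#' @title Dense autoencoder core
#' @description
#' All four autoencoders share a fully connected architecture
#' input -> h1 (ReLU) -> bottleneck (linear) -> h1 (ReLU) -> input (linear),
#' trained full-batch with Adam under a weighted sum-of-squares
#' reconstruction loss, optionally with an L1 penalty on the weight matrices
#' and a graph-Laplacian smoothness penalty. Forward/backward passes are
#' plain dense matrix algebra; all randomness comes from the seed.
NULL

.relu <- function(x) x * (x > 0)

glorot_init <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

ae_init_params <- function(n_in, dims) {
  d1 <- dims[1]; d2 <- dims[2]
  list(W1 = glorot_init(n_in, d1), b1 = rep(0, d1),
       W2 = glorot_init(d1, d2),  b2 = rep(0, d2),
       W3 = glorot_init(d2, d1),  b3 = rep(0, d1),
       W4 = glorot_init(d1, n_in), b4 = rep(0, n_in))
}

ae_forward <- function(X, p) {
  A1 <- sweep(X %*% p$W1, 2, p$b1, `+`)
  H1 <- .relu(A1)
  Z <- sweep(H1 %*% p$W2, 2, p$b2, `+`)            # linear bottleneck
  A3 <- sweep(Z %*% p$W3, 2, p$b3, `+`)
  H3 <- .relu(A3)
  Xhat <- sweep(H3 %*% p$W4, 2, p$b4, `+`)
  list(A1 = A1, H1 = H1, Z = Z, A3 = A3, H3 = H3, Xhat = Xhat)
}

# dXhat: gradient of the loss wrt the output matrix
ae_backward <- function(X, p, fwd, dXhat) {
  dW4 <- crossprod(fwd$H3, dXhat); db4 <- colSums(dXhat)
  dH3 <- tcrossprod(dXhat, p$W4) * (fwd$A3 > 0)
  dW3 <- crossprod(fwd$Z, dH3);   db3 <- colSums(dH3)
  dZ <- tcrossprod(dH3, p$W3)
  dW2 <- crossprod(fwd$H1, dZ);   db2 <- colSums(dZ)
  dH1 <- tcrossprod(dZ, p$W2) * (fwd$A1 > 0)
  dW1 <- crossprod(X, dH1);       db1 <- colSums(dH1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

ae_weight_l1 <- function(p) {
  sum(abs(p$W1)) + sum(abs(p$W2)) + sum(abs(p$W3)) + sum(abs(p$W4))
}

#' Train a dense autoencoder under a weighted reconstruction loss
#'
#' The loss is `sum(entry_weight * (X - Xhat)^2) + l1 * sum(|W|)`
#' (+ `2 * smooth_weight * tr(Xhat' L Xhat)` when a graph Laplacian penalty
#' is requested). This is the shared trainer behind the feature, cluster and
#' imputation autoencoders.
#'
#' @param X N x G input matrix (log space).
#' @param entry_weight N x G per-entry loss weight matrix (NULL = all ones).
#' @param dims encoder hidden/bottleneck sizes, default c(512, 128).
#' @param lr Adam learning rate.
#' @param epochs number of full-batch epochs (0 = initialization forward
#'   pass only).
#' @param seed RNG seed for weight initialization.
#' @param l1 L1 penalty strength on the four weight matrices (biases exempt).
#' @param laplacian optional N x N graph Laplacian for the pairwise
#'   smoothness penalty.
#' @param smooth_weight strength of the smoothness penalty.
#' @param init optional parameter list from a previous fit to warm-start
#'   from (continuation training); the seed then only matters if shapes
#'   mismatch.
#' @return List: `params`, `embedding` (N x dims[2]), `Xhat`, `loss_trace`.
#' @export
train_dense_ae <- function(X, entry_weight = NULL, dims = c(512, 128),
                           lr = 1e-3, epochs = 500, seed = 1, l1 = 0,
                           laplacian = NULL, smooth_weight = 0,
                           init = NULL) {
  X <- as.matrix(X)
  if (!is.null(entry_weight)) {
    entry_weight <- as.matrix(entry_weight)
    if (!all(dim(entry_weight) == dim(X)))
      stop("entry_weight shape ", paste(dim(entry_weight), collapse = "x"),
           " != X shape ", paste(dim(X), collapse = "x"))
  } else {
    entry_weight <- matrix(1, nrow(X), ncol(X))
  }
  set.seed(seed)
  p <- ae_init_params(ncol(X), dims)
  if (!is.null(init) &&
      all(mapply(function(a, b) identical(dim(a), dim(b)) &&
                   length(a) == length(b), init, p))) {
    p <- init
  }
  st <- adam_init(p)
  loss_trace <- numeric(epochs)
  fwd <- ae_forward(X, p)
  for (ep in seq_len(epochs)) {
    fwd <- ae_forward(X, p)
    E <- fwd$Xhat - X
    loss <- sum(entry_weight * E^2)
    dXhat <- 2 * entry_weight * E
    if (!is.null(laplacian) && smooth_weight > 0) {
      LX <- laplacian %*% fwd$Xhat
      loss <- loss + 2 * smooth_weight * sum(fwd$Xhat * LX)
      dXhat <- dXhat + 4 * smooth_weight * LX
    }
    if (l1 > 0) loss <- loss + l1 * ae_weight_l1(p)
    if (!is.finite(loss))
      stop("non-finite loss at epoch ", ep,
           " (lr = ", lr, "); aborting training")
    loss_trace[ep] <- loss
    g <- ae_backward(X, p, fwd, dXhat)
    if (l1 > 0) {
      for (w in c("W1", "W2", "W3", "W4")) g[[w]] <- g[[w]] + l1 * sign(p[[w]])
    }
    upd <- adam_step(p, g, st, lr = lr)
    p <- upd$params
    st <- upd$state
  }
  fwd <- ae_forward(X, p)
  list(params = p, embedding = fwd$Z, Xhat = fwd$Xhat,
       loss_trace = loss_trace)
}
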