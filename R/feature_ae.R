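#' Feature-autoencoder reconstruction loss
#'
#' `(1 - alpha) * sum((X - Xhat)^2) + alpha * sum((X - Xhat)^2 * trs_weight)`.
#' With `alpha = 0` this is the plain sum-of-squares reconstruction error;
#' the TRS term up-weights entries sitting in a regulated (non-baseline)
#' mixture component of their gene's LTMG fit.
#'
#' @param X,Xhat input and reconstructed matrices (same shape).
#' @param trs_weight per-entry TRS weight matrix (see [trs_weight()]); may
#'   be NULL when `alpha = 0`.
#' @param alpha TRS regularization mix in `[0, 1]`.
#' @return Scalar loss.
#' @export
feature_ae_loss <- function(X, Xhat, trs_weight = NULL, alpha = 0) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!all(dim(X) == dim(Xhat)))
    stop("X and Xhat shapes differ: ", paste(dim(X), collapse = "x"), " vs ",
         paste(dim(Xhat), collapse = "x"))
  sq <- (X - Xhat)^2
  if (alpha == 0) return(sum(sq))
  if (is.null(trs_weight)) stop("alpha > 0 requires trs_weight")
  if (!all(dim(trs_weight) == dim(X))) stop("trs_weight shape mismatch")
  (1 - alpha) * sum(sq) + alpha * sum(sq * trs_weight)
}

#' Reconstructed-matrix container
#' @param values reconstructed N x G matrix.
#' @param source which autoencoder produced it.
#' @return An object of class `reconstructed_matrix`.
#' @export
reconstructed_matrix <- function(values,
                                 source = c("feature_ae", "cluster_ae",
                                            "imputation_ae")) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("reconstructed matrix contains non-finite values")
  structure(list(values = values, source = source),
            class = "reconstructed_matrix")
}

#' @export
print.reconstructed_matrix <- function(x, ...) {
  cat("<reconstructed_matrix> ", nrow(x$values), " x ", ncol(x$values),
      " from ", x$source, "\n", sep = "")
  invisible(x)
}

#' Train the feature autoencoder
#'
#' Fully connected encoder (G -> dims[1] -> dims[2]) and mirrored decoder,
#' trained full-batch by Adam under [feature_ae_loss()]. The per-entry loss
#' weight is `(1 - alpha) + alpha * trs_weight`.
#'
#' @param X an [expression_matrix()] (log-normalized) or plain matrix.
#' @param trs a `trs_matrix` from [assign_trs()], or NULL when `alpha = 0`.
#' @param dims hidden and bottleneck sizes (default c(512, 128)).
#' @param lr,epochs,seed Adam training settings.
#' @param alpha TRS mix weight.
#' @param trs_mode weight mode passed to [trs_weight()].
#' @param init optional parameter list from a previous fit to warm-start
#'   from.
#' @return List: `embedding` (N x dims[2]), `reconstructed`
#'   (a `reconstructed_matrix`), `loss_trace`, `params`.
#' @export
train_feature_ae <- function(X, trs = NULL, dims = c(512, 128), lr = 1e-3,
                             epochs = 500, seed = 1, alpha = 0.5,
                             trs_mode = "binary", init = NULL) {
  xm <- if (inherits(X, "expression_matrix")) X$values else as.matrix(X)
  w <- NULL
  if (alpha > 0) {
    tw <- trs_weight(trs, trs_mode)
    if (is.null(tw)) {
      alpha <- 0
    } else {
      w <- (1 - alpha) + alpha * tw
    }
  }
  fit <- train_dense_ae(xm, entry_weight = w, dims = dims, lr = lr,
                        epochs = epochs, seed = seed, init = init)
  rec <- fit$Xhat
  dimnames(rec) <- dimnames(xm)
  list(embedding = fit$embedding,
       reconstructed = reconstructed_matrix(rec, "feature_ae"),
       loss_trace = fit$loss_trace, params = fit$params)
}
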