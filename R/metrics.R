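#' @name metrics
#' @title Imputation and clustering evaluation metrics
#' @description
#' Pair-counting (ARI, Fowlkes-Mallows), information-theoretic (AMI, NMI,
#' homogeneity, completeness, V-measure), geometric (silhouette,
#' Davies-Bouldin) clustering scores, the masked-entry imputation
#' statistics (L1 mean/median/max, cosine similarity, RMSE), and the
#' synthetic-dropout corruption protocol that scores recovery on exactly
#' the flipped entries.
NULL

#' Flip a fraction of non-zero entries to zero
#'
#' Uniformly samples `round(rate * nnz)` distinct non-zero positions under
#' the given seed and sets them to zero, emulating additional technical
#' dropout.
#'
#' @param X numeric matrix with at least one non-zero entry.
#' @param rate fraction of non-zero entries to flip, in (0, 1).
#' @param seed RNG seed.
#' @return List: `corrupted` matrix and `mask` (a `dropout_mask` with
#'   `flipped_indices` as a 2-column cell/gene index matrix, `rate`,
#'   `seed`).
#' @export
apply_synthetic_dropout <- function(X, rate, seed = 1) {
  stopifnot(rate > 0, rate < 1)
  X <- as.matrix(X)
  nz <- which(X != 0)
  n_flip <- round(rate * length(nz))
  if (n_flip == 0)
    stop("round(rate * nnz) = 0: nothing to flip (nnz = ", length(nz), ")")
  set.seed(seed)
  flip <- sample(nz, n_flip)
  corrupted <- X
  corrupted[flip] <- 0
  idx <- arrayInd(flip, dim(X))
  colnames(idx) <- c("cell", "gene")
  mask <- structure(list(flipped_indices = idx, rate = rate, seed = seed,
                         linear_indices = flip),
                    class = "dropout_mask")
  list(corrupted = corrupted, mask = mask)
}

#' Imputation recovery statistics
#'
#' Per-entry absolute deviations |x - y| summarized as mean/median/max,
#' per-row cosine similarity `x.y / (||x|| ||y||)` averaged over rows
#' (zero-norm rows skipped and counted), and RMSE. With
#' `scope = "masked_only"` (the benchmark default) each row vector is
#' restricted to that row's masked positions.
#'
#' @param original,imputed matrices of equal shape.
#' @param mask a `dropout_mask` (required for `scope = "masked_only"`).
#' @param scope `"masked_only"` or `"all"`.
#' @param axis `"cells"` (rows are cells, default) or `"genes"`.
#' @return List: `l1_mean`, `l1_median`, `l1_max`, `cosine`, `rmse`,
#'   `n_entries`, `n_rows_skipped`.
#' @export
imputation_metrics <- function(original, imputed, mask = NULL,
                               scope = c("masked_only", "all"),
                               axis = c("cells", "genes")) {
  scope <- match.arg(scope)
  axis <- match.arg(axis)
  x <- as.matrix(original)
  y <- as.matrix(imputed)
  if (!all(dim(x) == dim(y))) stop("original and imputed shapes differ")
  if (axis == "genes") {
    x <- t(x); y <- t(y)
  }
  if (scope == "masked_only") {
    if (is.null(mask)) stop("scope = 'masked_only' requires a dropout mask")
    sel <- matrix(FALSE, nrow(x), ncol(x))
    idx <- mask$flipped_indices
    if (axis == "genes") idx <- idx[, c(2, 1), drop = FALSE]
    sel[idx] <- TRUE
  } else {
    sel <- matrix(TRUE, nrow(x), ncol(x))
  }
  devs <- abs(x - y)[sel]
  if (!length(devs)) stop("empty evaluation scope")
  cos_rows <- numeric(0)
  skipped <- 0L
  for (i in seq_len(nrow(x))) {
    s <- sel[i, ]
    if (!any(s)) next
    xi <- x[i, s]; yi <- y[i, s]
    nx <- sqrt(sum(xi^2)); ny <- sqrt(sum(yi^2))
    if (nx == 0 || ny == 0) {
      skipped <- skipped + 1L
      next
    }
    cos_rows <- c(cos_rows, sum(xi * yi) / (nx * ny))
  }
  list(l1_mean = mean(devs), l1_median = stats::median(devs),
       l1_max = max(devs),
       cosine = if (length(cos_rows)) mean(cos_rows) else NA_real_,
       rmse = sqrt(mean((x - y)[sel]^2)),
       n_entries = length(devs), n_rows_skipped = skipped)
}

.contingency <- function(a, b) {
  table(factor(a), factor(b))
}

#' Adjusted Rand index
#'
#' Contingency-table formulation of `(RI - E[RI]) / (max(RI) - E[RI])`;
#' 1 for identical partitions up to relabeling.
#'
#' @param true_labels,pred_labels label vectors of equal length >= 2.
#' @return Scalar ARI (<= 1; can be negative).
#' @export
ari <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors differ in length")
  n <- length(true_labels)
  if (n < 2) stop("need at least 2 observations")
  ct <- .contingency(true_labels, pred_labels)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(ct))
  sum_a <- sum(ch2(rowSums(ct)))
  sum_b <- sum(ch2(colSums(ct)))
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)   # both partitions degenerate/identical
  (sum_ij - expected) / (mx - expected)
}

.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# expected mutual information under the hypergeometric model
.expected_mi <- function(a, b, n) {
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      ai <- a[i]; bj <- b[j]
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      nij <- lo:hi
      term <- (nij / n) * log(n * nij / (ai * bj))
      lw <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
        lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum(term * exp(lw))
    }
  }
  emi
}

#' Information-theoretic clustering scores
#'
#' Mutual information and entropies (natural log) from the contingency
#' table give: NMI = MI / mean(H(x), H(y)); AMI with the hypergeometric
#' expected MI and the same mean normalization; homogeneity
#' `1 - H(true|pred)/H(true)`; completeness `1 - H(pred|true)/H(pred)`;
#' V-measure = harmonic mean of homogeneity and completeness. Degenerate
#' zero-entropy cases follow the usual conventions (perfect score when
#' nothing can be split or merged).
#'
#' @param true_labels,pred_labels label vectors of equal length.
#' @return List: `ami`, `nmi`, `cs`, `vms`, `hs`.
#' @export
information_scores <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors differ in length")
  n <- length(true_labels)
  ct <- as.matrix(.contingency(true_labels, pred_labels))
  a <- rowSums(ct)
  b <- colSums(ct)
  hx <- .entropy(a)
  hy <- .entropy(b)
  p <- ct / n
  nzi <- which(ct > 0, arr.ind = TRUE)
  mi <- sum(p[nzi] * log(p[nzi] / (a[nzi[, 1]] / n * b[nzi[, 2]] / n)))
  mi <- max(mi, 0)
  # conditional entropies
  h_x_given_y <- hx - mi   # H(true | pred)
  h_y_given_x <- hy - mi   # H(pred | true)
  hs <- if (hx == 0) 1 else 1 - h_x_given_y / hx
  cs <- if (hy == 0) 1 else 1 - h_y_given_x / hy
  vms <- if (hs + cs == 0) 0 else 2 * hs * cs / (hs + cs)
  mean_h <- (hx + hy) / 2
  nmi <- if (mean_h == 0) 1 else mi / mean_h
  if (mean_h == 0) {
    ami <- 1
  } else {
    emi <- .expected_mi(a, b, n)
    denom <- mean_h - emi
    ami <- if (abs(denom) < 1e-15) 1 else (mi - emi) / denom
  }
  list(ami = ami, nmi = nmi, cs = cs, vms = vms, hs = hs)
}

#' Fowlkes-Mallows score
#'
#' Pair-counting `TP / sqrt((TP + FP) (TP + FN))` where TP counts pairs
#' placed together in both partitions; 0 by convention when either
#' partition has no same-cluster pairs.
#'
#' @param true_labels,pred_labels label vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
fowlkes_mallows <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors differ in length")
  ct <- as.matrix(.contingency(true_labels, pred_labels))
  ch2 <- function(x) x * (x - 1) / 2
  tp <- sum(ch2(ct))
  pa <- sum(ch2(rowSums(ct)))
  pb <- sum(ch2(colSums(ct)))
  if (pa == 0 || pb == 0) return(0)
  tp / sqrt(pa * pb)
}

#' Silhouette and Davies-Bouldin scores
#'
#' Silhouette: per object, `s = (b - a) / max(a, b)` with a = mean
#' intra-cluster distance (self excluded) and b = min over other clusters
#' of the mean distance; singleton clusters score 0; the mean s is
#' returned. Davies-Bouldin: mean over clusters of the worst
#' `(S_i + S_j) / d(c_i, c_j)` ratio, with S the mean distance to the
#' cluster centroid. Euclidean metric throughout.
#'
#' @param X N x d data or embedding matrix.
#' @param labels cluster labels (>= 2 clusters).
#' @return List: `silhouette`, `dbs`.
#' @export
geometry_scores <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("need at least 2 clusters")
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) {
      s[i] <- 0
      next
    }
    a <- sum(d[i, own]) / (length(own) - 1)
    b <- min(vapply(ks[ks != labels[i]], function(k)
      mean(d[i, labels == k]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  centroids <- do.call(rbind, lapply(ks, function(k)
    colMeans(X[labels == k, , drop = FALSE])))
  spread <- vapply(seq_along(ks), function(k) {
    idx <- labels == ks[k]
    mean(sqrt(rowSums((X[idx, , drop = FALSE] -
                         matrix(centroids[k, ], sum(idx), ncol(X),
                                byrow = TRUE))^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(centroids))
  db <- mean(vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j)
      (spread[i] + spread[j]) / cd[i, j], numeric(1)))
  }, numeric(1)))
  list(silhouette = mean(s), dbs = db)
}

#' Full metric report
#'
#' Convenience wrapper bundling the imputation statistics (when a mask is
#' given) and all clustering scores (when labels are given).
#'
#' @param original,imputed matrices for the imputation part (optional).
#' @param mask a `dropout_mask` (optional).
#' @param true_labels,pred_labels partitions for the clustering part
#'   (optional).
#' @param embedding matrix for silhouette/DBS (optional; defaults to
#'   `imputed`).
#' @return List with `imputation` and `clustering` sublists (either may be
#'   NULL).
#' @export
metric_report <- function(original = NULL, imputed = NULL, mask = NULL,
                          true_labels = NULL, pred_labels = NULL,
                          embedding = NULL) {
  imp <- NULL
  if (!is.null(original) && !is.null(imputed)) {
    imp <- imputation_metrics(original, imputed, mask,
                              scope = if (is.null(mask)) "all" else
                                "masked_only")
  }
  clu <- NULL
  if (!is.null(true_labels) && !is.null(pred_labels)) {
    clu <- c(list(ari = ari(true_labels, pred_labels),
                  fms = fowlkes_mallows(true_labels, pred_labels)),
             information_scores(true_labels, pred_labels))
    emb <- embedding %||% imputed
    if (!is.null(emb) && length(unique(pred_labels)) >= 2) {
      clu <- c(clu, geometry_scores(emb, pred_labels))
    }
  }
  list(imputation = imp, clustering = clu)
}
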