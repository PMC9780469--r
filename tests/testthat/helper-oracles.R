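# Independent brute-force implementations used as oracles. These are kept
# deliberately naive (scalar loops, exhaustive pair enumeration) and share no
# code with the package internals.

oracle_lognorm <- function(counts, scale_factor) {
  out <- counts
  for (i in seq_len(nrow(counts))) {
    lib <- sum(counts[i, ])
    for (j in seq_len(ncol(counts))) {
      out[i, j] <- log(1 + scale_factor * counts[i, j] / lib)
    }
  }
  out
}

oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  np <- n * (n - 1) / 2
  ri <- (s11 + s00) / np
  e_ri <- ((s11 + s10) * (s11 + s01) + (s01 + s00) * (s10 + s00)) / np^2
  max_ri <- ((s11 + s10) + (s11 + s01)) / (2 * np) +
    ((s01 + s00) + (s10 + s00)) / (2 * np)
  if (max_ri == e_ri) return(1)
  (ri - e_ri) / (max_ri - e_ri)
}

oracle_fms <- function(a, b) {
  n <- length(a)
  tp <- fp <- fn <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) tp <- tp + 1
      else if (!sa && sb) fp <- fp + 1
      else if (sa && !sb) fn <- fn + 1
    }
  }
  if (tp + fp == 0 || tp + fn == 0) return(0)
  tp / sqrt((tp + fp) * (tp + fn))
}

oracle_entropy_scores <- function(a, b) {
  n <- length(a)
  ua <- unique(a)
  ub <- unique(b)
  ent <- function(labs, u) {
    h <- 0
    for (v in u) {
      p <- sum(labs == v) / n
      if (p > 0) h <- h - p * log(p)
    }
    h
  }
  hx <- ent(a, ua)
  hy <- ent(b, ub)
  mi <- 0
  for (va in ua) {
    for (vb in ub) {
      pij <- sum(a == va & b == vb) / n
      if (pij > 0) {
        mi <- mi + pij * log(pij / ((sum(a == va) / n) * (sum(b == vb) / n)))
      }
    }
  }
  mi <- max(mi, 0)
  hs <- if (hx == 0) 1 else 1 - (hx - mi) / hx
  cs <- if (hy == 0) 1 else 1 - (hy - mi) / hy
  vms <- if (hs + cs == 0) 0 else 2 * hs * cs / (hs + cs)
  nmi <- if ((hx + hy) / 2 == 0) 1 else mi / ((hx + hy) / 2)
  list(mi = mi, hx = hx, hy = hy, nmi = nmi, cs = cs, vms = vms, hs = hs)
}

oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) {
      s[i] <- 0
      next
    }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (k in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(vapply(which(labels == k), function(j) d(i, j),
                              numeric(1))))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

oracle_dbs <- function(X, labels) {
  ks <- sort(unique(labels))
  cent <- lapply(ks, function(k) colMeans(X[labels == k, , drop = FALSE]))
  sp <- vapply(seq_along(ks), function(k) {
    idx <- which(labels == ks[k])
    mean(vapply(idx, function(i) sqrt(sum((X[i, ] - cent[[k]])^2)),
                numeric(1)))
  }, numeric(1))
  mean(vapply(seq_along(ks), function(i) {
    max(vapply(setdiff(seq_along(ks), i), function(j)
      (sp[i] + sp[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2)), numeric(1)))
  }, numeric(1)))
}

oracle_imputation <- function(x, y, sel) {
  devs <- c()
  sq <- c()
  coss <- c()
  for (i in seq_len(nrow(x))) {
    xi <- c(); yi <- c()
    for (j in seq_len(ncol(x))) {
      if (sel[i, j]) {
        devs <- c(devs, abs(x[i, j] - y[i, j]))
        sq <- c(sq, (x[i, j] - y[i, j])^2)
        xi <- c(xi, x[i, j]); yi <- c(yi, y[i, j])
      }
    }
    if (length(xi)) {
      nx <- sqrt(sum(xi^2)); ny <- sqrt(sum(yi^2))
      if (nx > 0 && ny > 0) coss <- c(coss, sum(xi * yi) / (nx * ny))
    }
  }
  list(l1_mean = mean(devs), l1_median = median(devs), l1_max = max(devs),
       cosine = mean(coss), rmse = sqrt(mean(sq)))
}

# GCN propagation oracle: scalar-loop Atilde %*% H %*% W then ReLU
oracle_gcn <- function(At, H, W) {
  n <- nrow(H)
  HW <- matrix(0, n, ncol(W))
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(W))) {
      HW[i, j] <- sum(H[i, ] * W[, j])
    }
  }
  S <- matrix(0, n, ncol(W))
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(W))) {
      S[i, j] <- sum(At[i, ] * HW[, j])
    }
  }
  pmax(S, 0)
}

oracle_attention <- function(H, W, mask) {
  n <- nrow(H)
  M <- H %*% W
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(mask[i, ] > 0)
    e <- vapply(nb, function(j) sum(M[i, ] * M[j, ]), numeric(1))
    w <- exp(e - max(e))
    A[i, nb] <- w / sum(w)
  }
  A
}

# Batched scikit-learn oracle for the clustering metric suite. `instances`
# is a list of lists with elements `true`, `pred` and optionally `X`.
sklearn_metrics <- function(instances) {
  py <- Sys.which("python")
  if (py == "") return(NULL)
  inp <- tempfile(fileext = ".json")
  outp <- tempfile(fileext = ".json")
  script <- tempfile(fileext = ".py")
  jsonlite::write_json(instances, inp, digits = NA)
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from sklearn import metrics as sm",
    "inst = json.load(open(sys.argv[1]))",
    "out = []",
    "for d in inst:",
    "    t = np.asarray(d['true']).ravel()",
    "    p = np.asarray(d['pred']).ravel()",
    "    r = {",
    "        'ari': sm.adjusted_rand_score(t, p),",
    "        'ami': sm.adjusted_mutual_info_score(t, p),",
    "        'nmi': sm.normalized_mutual_info_score(t, p),",
    "        'hs': sm.homogeneity_score(t, p),",
    "        'cs': sm.completeness_score(t, p),",
    "        'vms': sm.v_measure_score(t, p),",
    "        'fms': sm.fowlkes_mallows_score(t, p),",
    "    }",
    "    if 'X' in d and d['X'] is not None:",
    "        X = np.asarray(d['X'])",
    "        r['silhouette'] = sm.silhouette_score(X, p)",
    "        r['dbs'] = sm.davies_bouldin_score(X, p)",
    "    out.append(r)",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  status <- system2(py, c(script, inp, outp), stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(outp)) return(NULL)
  jsonlite::fromJSON(outp, simplifyDataFrame = FALSE)
}
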