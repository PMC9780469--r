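#' Cluster assignment container
#'
#' @param labels 0-based integer vector; relabeled to be contiguous.
#' @return A `cluster_assignment`: `labels`, `n_clusters`,
#'   `same_type_matrix` (B, symmetric 0/1 with unit diagonal).
#' @export
cluster_assignment <- function(labels) {
  labels <- as.integer(factor(labels)) - 1L
  structure(list(labels = labels,
                 n_clusters = length(unique(labels)),
                 same_type_matrix = same_type_matrix(labels)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$labels), " cells in ",
      x$n_clusters, " clusters: ",
      paste(table(x$labels), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Same-cell-type relationship matrix B
#' @param labels integer label vector.
#' @return N x N matrix with `B_ij = 1` iff `labels_i == labels_j`.
#' @export
same_type_matrix <- function(labels) {
  outer(labels, labels, `==`) * 1
}

#' Number of clusters by Louvain community detection
#'
#' Runs Louvain modularity optimization on the cell graph and returns the
#' community count after merging communities smaller than
#' `min_cluster_size` into their nearest community (by mean embedding
#' distance when an embedding is supplied, otherwise into the largest).
#'
#' @param g a `cell_graph`.
#' @param seed RNG seed (Louvain's vertex order is randomized).
#' @param resolution Louvain resolution parameter.
#' @param min_cluster_size communities below this size are merged.
#' @param embedding optional N x d embedding for nearest-community merging.
#' @return Integer number of clusters k.
#' @export
louvain_n_clusters <- function(g, seed = 1, resolution = 1,
                               min_cluster_size = 10, embedding = NULL) {
  stopifnot(inherits(g, "cell_graph"))
  if (g$n_cells == 0 || sum(g$adjacency) == 0) stop("empty graph")
  gr <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                            weighted = TRUE)
  set.seed(seed)
  comm <- igraph::membership(igraph::cluster_louvain(gr,
                                                     resolution = resolution))
  sizes <- table(comm)
  small <- as.integer(names(sizes)[sizes < min_cluster_size])
  big <- as.integer(names(sizes)[sizes >= min_cluster_size])
  if (length(big) == 0) return(1L)
  if (length(small)) {
    for (s in small) {
      idx <- which(comm == s)
      if (!is.null(embedding)) {
        cs <- vapply(big, function(b) {
          mean(as.matrix(stats::dist(rbind(
            colMeans(embedding[idx, , drop = FALSE]),
            colMeans(embedding[comm == b, , drop = FALSE]))))[1, 2])
        }, numeric(1))
        comm[idx] <- big[which.min(cs)]
      } else {
        comm[idx] <- big[which.max(sizes[as.character(big)])]
      }
    }
  }
  length(unique(comm))
}

kmeanspp_centers <- function(Z, k) {
  n <- nrow(Z)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((Z - Z[rep(centers[1], n), , drop = FALSE])^2)
  for (i in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1] <- sample.int(n, 1, prob = p)
    nd <- rowSums((Z - Z[rep(centers[i + 1], n), , drop = FALSE])^2)
    d2 <- pmin(d2, nd)
  }
  Z[centers, , drop = FALSE]
}

#' Cluster cells by k-means on an embedding
#'
#' Lloyd iterations with k-means++ initialization, `n_init` restarts under
#' a fixed seed; labels are canonicalized by descending cluster size. If k
#' exceeds the number of distinct rows it is reduced (logged).
#'
#' @param Z N x d embedding (a `graph_embedding` or matrix).
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param n_init number of restarts.
#' @return A [cluster_assignment()].
#' @export
kmeans_assign <- function(Z, k, seed = 1, n_init = 10) {
  zm <- if (inherits(Z, "graph_embedding")) Z$Z else as.matrix(Z)
  n <- nrow(zm)
  if (k > n) stop("k (", k, ") exceeds the number of cells (", n, ")")
  n_distinct <- nrow(unique(zm))
  if (k > n_distinct) {
    message("k reduced from ", k, " to ", n_distinct,
            " (distinct embedding rows)")
    k <- n_distinct
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    cen <- kmeanspp_centers(zm, k)
    km <- tryCatch(
      stats::kmeans(zm, centers = cen, iter.max = 100, algorithm = "Lloyd"),
      error = function(e) NULL,
      warning = function(w) suppressWarnings(
        stats::kmeans(zm, centers = cen, iter.max = 100,
                      algorithm = "Lloyd")))
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed for every restart")
  lab <- best$cluster
  # canonical order: descending size, ties by first occurrence
  sizes <- table(lab)
  first <- vapply(names(sizes), function(l) match(l, lab), integer(1))
  ord <- names(sizes)[order(-as.integer(sizes), first)]
  cluster_assignment(match(as.character(lab), ord) - 1L)
}

#' Run the iterative imputation/clustering pipeline
#'
#' Each round: feature autoencoder on the current expression matrix ->
#' KNN cell graph (round 1 from the feature-AE embedding, later rounds from
#' the previous GAE embedding) -> quantile pruning -> adjacency mixing
#' (round 1: symmetric normalization; later: `mu * L0 + (1-mu) * RowNorm(A)`
#' with L0 the normalized round-1 pruned graph) -> graph autoencoder ->
#' Louvain cluster count -> k-means labels -> per-cluster autoencoders,
#' whose output feeds the next round. The loop stops when the mixed
#' adjacency's relative Frobenius change falls below `tol_adj` and the ARI
#' between consecutive labelings exceeds `tol_ari`, or at `max_rounds`
#' (with a warning). The imputation autoencoder is then trained once on the
#' original matrix with the final graph and cell types.
#'
#' With `use_gae = FALSE` the graph autoencoder is skipped and clustering
#' runs directly on the feature-AE embedding (ablation).
#'
#' @param X preprocessed (log-normalized) [expression_matrix()] or matrix.
#' @param trs a `trs_matrix` from [assign_trs()], or NULL.
#' @param config a [sgi_config()] list.
#' @return List: `assignment` (a `cluster_assignment`), `imputed` (a
#'   `reconstructed_matrix` from the imputation AE), `imputed_zeros`
#'   (original matrix with zeros replaced), `state` (round, adjacency_delta,
#'   label_ari_prev, converged, history), `graph`, `embedding`.
#' @export
run_iterative_pipeline <- function(X, trs = NULL, config = sgi_config()) {
  cfg <- config
  xm <- if (inherits(X, "expression_matrix")) X$values else as.matrix(X)
  n <- nrow(xm)
  knn_k <- cfg$knn_k %||% max(5, round(n / 10))
  seeds <- sgi_stage_seeds(cfg$seed)

  history <- list()
  prev_At <- NULL
  prev_labels <- NULL
  L0 <- NULL
  gae_embed <- NULL
  current <- xm
  converged <- FALSE
  delta <- NA_real_
  ari_prev <- NA_real_
  graph <- NULL
  assignment <- NULL
  fae_init <- NULL
  gae_init <- NULL
  cae_init <- NULL

  for (round in seq_len(cfg$max_rounds)) {
    warm <- cfg$warm_start && round > 1
    ae_ep <- if (warm) cfg$continue_epochs %||% ceiling(cfg$ae_epochs / 2)
      else cfg$ae_epochs
    gae_ep <- if (warm) cfg$continue_epochs %||% ceiling(cfg$gae_epochs / 2)
      else cfg$gae_epochs
    fae <- train_feature_ae(current, trs, dims = cfg$ae_dims, lr = cfg$ae_lr,
                            epochs = ae_ep, seed = seeds$feature_ae,
                            alpha = cfg$alpha, trs_mode = cfg$trs_mode,
                            init = fae_init)
    if (cfg$warm_start) fae_init <- fae$params
    knn_input <- if (round == 1 || is.null(gae_embed) ||
                     cfg$knn_source == "feature") fae$embedding else gae_embed
    g <- build_knn_graph(knn_input, knn_k)
    g <- prune_graph(g, knn_input, cfg$prune_quantile)
    if (round == 1) {
      At <- normalize_adjacency(g)
      L0 <- At
    } else {
      At <- update_adjacency_iteration(L0, g, mix = cfg$mix)
    }

    if (cfg$use_gae) {
      ge <- train_gae(At, fae$reconstructed$values, heads = cfg$heads,
                      dims = cfg$gae_dims, lr = cfg$gae_lr,
                      epochs = gae_ep, seed = seeds$gae, init = gae_init)
      if (cfg$warm_start) gae_init <- ge$weights
      gae_embed <- ge$Z
      cluster_embed <- ge$Z
    } else {
      ge <- NULL
      cluster_embed <- fae$embedding
    }

    k <- louvain_n_clusters(g, seed = seeds$louvain,
                            resolution = cfg$louvain_resolution,
                            min_cluster_size = cfg$min_cluster_size,
                            embedding = cluster_embed)
    assignment <- kmeans_assign(cluster_embed, k, seed = seeds$kmeans)

    cae <- train_cluster_ae(fae$reconstructed, assignment, trs,
                            dims = cfg$ae_dims, lr = cfg$ae_lr,
                            epochs = ae_ep, seed = seeds$cluster_ae,
                            alpha = cfg$alpha, trs_mode = cfg$trs_mode,
                            min_cluster_size = cfg$min_cluster_size,
                            init = cae_init)
    if (cfg$warm_start) cae_init <- attr(cae, "params")

    delta <- if (is.null(prev_At)) NA_real_ else
      adjacency_delta(At$matrix, prev_At)
    ari_prev <- if (is.null(prev_labels)) NA_real_ else
      ari(prev_labels, assignment$labels)
    history[[round]] <- list(
      round = round, k = k, adjacency_delta = delta,
      label_ari_prev = ari_prev,
      feature_loss = unname(utils::tail(fae$loss_trace, 1)),
      gae_loss = if (is.null(ge)) NA_real_ else
        unname(utils::tail(ge$loss_trace, 1)),
      cluster_sizes = paste(table(assignment$labels), collapse = "/"))

    graph <- g
    prev_At <- At$matrix
    prev_labels <- assignment$labels
    current <- cae$values

    if (!is.na(delta) && !is.na(ari_prev) &&
        delta < cfg$tol_adj && ari_prev > cfg$tol_ari) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("iteration reached max_rounds = ", cfg$max_rounds,
            " without meeting the convergence criteria; returning last state")
    converged <- TRUE  # by definition at max_rounds
    reason <- "max_rounds"
  } else {
    reason <- "criteria"
  }

  imp <- train_imputation_ae(xm, graph, assignment, trs,
                             dims = cfg$ae_dims, lr = cfg$ae_lr,
                             epochs = cfg$ae_epochs,
                             seed = seeds$imputation_ae,
                             alpha = cfg$alpha, beta = cfg$beta,
                             gamma1 = cfg$gamma1, gamma2 = cfg$gamma2,
                             trs_mode = cfg$trs_mode,
                             graph_penalty = cfg$graph_penalty)

  state <- list(round = length(history), adjacency_delta = delta,
                label_ari_prev = ari_prev, converged = converged,
                reason = reason, history = history)
  list(assignment = assignment, imputed = imp$reconstructed,
       imputed_zeros = impute_zeros(xm, imp$reconstructed),
       state = state, graph = graph, embedding = gae_embed %||% NULL)
}

#' Iteration history as a data frame
#' @param state the `state` element returned by [run_iterative_pipeline()].
#' @return data.frame with one row per round.
#' @export
iteration_history <- function(state) {
  do.call(rbind, lapply(state$history, function(h)
    data.frame(round = h$round, k = h$k,
               adjacency_delta = h$adjacency_delta,
               label_ari_prev = h$label_ari_prev,
               feature_loss = h$feature_loss, gae_loss = h$gae_loss,
               cluster_sizes = h$cluster_sizes)))
}
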