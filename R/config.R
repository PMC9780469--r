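#' Pipeline run configuration
#'
#' Collects every tunable parameter of the workflow with its default. The
#' single `seed` fans out to fixed per-stage seeds (see
#' [sgi_stage_seeds()]) so each stochastic stage is isolated and the whole
#' run is reproducible from the config alone.
#'
#' @param seed global RNG seed.
#' @param min_cells_frac,min_genes_per_cell quality filters (preprocess).
#' @param scale_factor library-size scale constant for log-normalization.
#' @param n_top_genes number of high-variance genes kept.
#' @param ltmg_k_max,ltmg_zcut LTMG BIC cap and censoring threshold.
#' @param knn_k KNN neighbor count; NULL = `max(5, round(N / 10))`.
#' @param prune_quantile per-node edge-length quantile cut.
#' @param mix adjacency iteration weight mu (default 0.5).
#' @param heads GAT attention heads K (0 disables attention; default 3).
#' @param gae_dims,gae_lr,gae_epochs graph-autoencoder settings.
#' @param ae_dims,ae_lr,ae_epochs dense-autoencoder settings (feature,
#'   cluster and imputation AEs).
#' @param alpha TRS mix weight; `beta` L1 strength; `gamma1`, `gamma2`
#'   graph/cell-type regularizer strengths.
#' @param beta,gamma1,gamma2 see `alpha`.
#' @param trs_mode TRS weighting mode ([trs_weight()]).
#' @param min_cluster_size smallest trainable/reportable cluster.
#' @param louvain_resolution Louvain resolution.
#' @param tol_adj,tol_ari,max_rounds outer-iteration stopping rules.
#' @param use_gae FALSE skips the graph autoencoder (ablation).
#' @param warm_start carry network parameters across outer rounds
#'   (continuation training) instead of re-initializing; rounds after the
#'   first then train `continue_epochs` epochs.
#' @param continue_epochs epochs for warm-started rounds; NULL = half the
#'   stage's epoch budget.
#' @param knn_source `"gae"`: rounds > 1 build the KNN graph from the GAE
#'   embedding; `"feature"`: always from the feature-AE embedding.
#' @param graph_penalty imputation graph-term reading
#'   ([imputation_loss()]).
#' @return A validated list of class `sgi_config`.
#' @export
sgi_config <- function(seed = 1,
                       min_cells_frac = 0.01, min_genes_per_cell = 200,
                       scale_factor = 1e4, n_top_genes = 2000,
                       ltmg_k_max = 5, ltmg_zcut = 0,
                       knn_k = NULL, prune_quantile = 0.97, mix = 0.5,
                       heads = 3, gae_dims = c(32, 16), gae_lr = 1e-3,
                       gae_epochs = 150,
                       ae_dims = c(512, 128), ae_lr = 1e-3, ae_epochs = 200,
                       alpha = 0.5, beta = 0.5, gamma1 = 0.1, gamma2 = 0.1,
                       trs_mode = "binary", min_cluster_size = 10,
                       louvain_resolution = 1,
                       tol_adj = 0.3, tol_ari = 0.99, max_rounds = 10,
                       use_gae = TRUE, warm_start = TRUE,
                       continue_epochs = NULL,
                       knn_source = c("feature", "gae"),
                       graph_penalty = c("weighted_error", "pairwise")) {
  knn_source <- match.arg(knn_source)
  graph_penalty <- match.arg(graph_penalty)
  stopifnot(seed == round(seed),
            min_cells_frac >= 0, min_cells_frac <= 1,
            min_genes_per_cell >= 0, scale_factor > 0, n_top_genes >= 1,
            ltmg_k_max >= 1, is.null(knn_k) || knn_k >= 1,
            prune_quantile > 0, prune_quantile <= 1,
            mix >= 0, mix <= 1, heads >= 0, heads == round(heads),
            length(gae_dims) == 2, length(ae_dims) == 2,
            gae_lr > 0, ae_lr > 0, gae_epochs >= 0, ae_epochs >= 0,
            alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            gamma1 >= 0, gamma2 >= 0, min_cluster_size >= 1,
            louvain_resolution > 0, tol_adj > 0,
            tol_ari > 0, tol_ari <= 1, max_rounds >= 1)
  structure(list(seed = as.integer(seed), min_cells_frac = min_cells_frac,
                 min_genes_per_cell = min_genes_per_cell,
                 scale_factor = scale_factor, n_top_genes = n_top_genes,
                 ltmg_k_max = ltmg_k_max, ltmg_zcut = ltmg_zcut,
                 knn_k = knn_k, prune_quantile = prune_quantile, mix = mix,
                 heads = as.integer(heads), gae_dims = gae_dims,
                 gae_lr = gae_lr, gae_epochs = gae_epochs,
                 ae_dims = ae_dims, ae_lr = ae_lr, ae_epochs = ae_epochs,
                 alpha = alpha, beta = beta, gamma1 = gamma1,
                 gamma2 = gamma2, trs_mode = trs_mode,
                 min_cluster_size = min_cluster_size,
                 louvain_resolution = louvain_resolution,
                 tol_adj = tol_adj, tol_ari = tol_ari,
                 max_rounds = max_rounds, use_gae = use_gae,
                 warm_start = warm_start, continue_epochs = continue_epochs,
                 knn_source = knn_source, graph_penalty = graph_penalty),
            class = "sgi_config")
}

#' Per-stage seeds derived from the global seed
#'
#' Fixed small offsets keep stage randomness isolated (a change in one
#' stage's draws cannot shift another's) while staying within 32-bit
#' integer range.
#'
#' @param seed global seed.
#' @return Named list of integer seeds.
#' @export
sgi_stage_seeds <- function(seed) {
  base <- as.integer(seed) %% 2000000000L
  list(feature_ae = base + 101L, gae = base + 211L, louvain = base + 401L,
       kmeans = base + 307L, cluster_ae = base + 503L,
       imputation_ae = base + 601L, simulate = base + 701L,
       dropout = base + 811L)
}
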