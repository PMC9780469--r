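#' Synthetic scRNA-seq dataset configuration
#'
#' The generator emulates the count regime the pipeline targets: balanced
#' cell clusters, per-gene baseline log-means, a fraction of genes
#' differentially expressed per cluster (log-shift drawn from
#' `U(de_shift)`), negative-binomial counts with a common overdispersion,
#' and logistic technical dropout whose probability decreases with true
#' expression: `plogis(dropout_mid - log_mean * dropout_slope)`.
#'
#' @param n_cells,n_genes,n_clusters dataset dimensions.
#' @param de_frac fraction of genes differentially expressed per cluster.
#' @param log_mean_range interval for baseline gene log-means (natural log
#'   of the NB mean).
#' @param de_shift interval for per-cluster DE log-mean shifts.
#' @param dispersion NB overdispersion (NB size = 1/dispersion).
#' @param dropout_mid,dropout_slope logistic dropout curve parameters.
#' @param seed RNG seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 200, n_genes = 300, n_clusters = 3,
                              de_frac = 0.2, log_mean_range = c(0, 2),
                              de_shift = c(1, 2), dispersion = 0.3,
                              dropout_mid = 0, dropout_slope = 1, seed = 1) {
  stopifnot(n_cells >= 1, n_genes >= 1, n_clusters >= 1,
            n_clusters <= n_cells, de_frac >= 0, de_frac <= 1,
            length(log_mean_range) == 2, dispersion > 0,
            dropout_slope >= 0)
  if (de_frac == 0 && n_clusters > 1)
    warning("de_frac = 0 with multiple clusters: clusters will be ",
            "indistinguishable")
  structure(list(n_cells = n_cells, n_genes = n_genes,
                 n_clusters = n_clusters, de_frac = de_frac,
                 log_mean_range = log_mean_range, de_shift = de_shift,
                 dispersion = dispersion, dropout_mid = dropout_mid,
                 dropout_slope = dropout_slope, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic count matrix with planted clusters
#'
#' @param cfg a [simulation_config()].
#' @return List: `counts` (an [expression_matrix()] of raw counts), `truth`
#'   (list with 0-based `labels`, `true_log_means` (clusters x genes),
#'   `dropout_mask` logical matrix of technical zeros applied to positive
#'   counts).
#' @export
generate_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cells; g <- cfg$n_genes; k <- cfg$n_clusters
  labels <- rep(seq_len(k) - 1L, length.out = n)
  base_lm <- stats::runif(g, cfg$log_mean_range[1], cfg$log_mean_range[2])
  lm <- matrix(base_lm, k, g, byrow = TRUE)
  n_de <- round(cfg$de_frac * g)
  for (cl in seq_len(k)) {
    if (n_de == 0) break
    de <- sample.int(g, n_de)
    lm[cl, de] <- lm[cl, de] + stats::runif(n_de, cfg$de_shift[1],
                                            cfg$de_shift[2])
  }
  mu <- exp(lm[labels + 1L, , drop = FALSE])
  counts <- matrix(stats::rnbinom(n * g, mu = mu, size = 1 / cfg$dispersion),
                   n, g)
  p_drop <- stats::plogis(cfg$dropout_mid -
                            lm[labels + 1L, , drop = FALSE] *
                            cfg$dropout_slope)
  drop <- matrix(stats::rbinom(n * g, 1, p_drop), n, g) == 1
  dropout_mask <- drop & counts > 0
  counts[drop] <- 0L
  cells <- sprintf("cell%03d", seq_len(n))
  genes <- sprintf("gene%04d", seq_len(g))
  dimnames(counts) <- list(cells, genes)
  dimnames(dropout_mask) <- dimnames(counts)
  list(counts = expression_matrix(counts, space = "raw_counts"),
       truth = list(labels = labels, true_log_means = lm,
                    dropout_mask = dropout_mask))
}

#' Draw from a left-censored Gaussian mixture
#'
#' Oracle input generator for the LTMG module: draws from the mixture and
#' records values at or below `censor_at` as `censor_at`.
#'
#' @param n sample size.
#' @param weights mixing probabilities (sum to 1).
#' @param means,sds component parameters.
#' @param censor_at censoring threshold (`-Inf` = no censoring).
#' @param seed RNG seed.
#' @return List: `values` (censored sample), `uncensored` (latent draws),
#'   `components` (1-based component of each draw).
#' @export
generate_censored_mixture <- function(n, weights, means, sds,
                                      censor_at = -Inf, seed = 1) {
  stopifnot(abs(sum(weights) - 1) < 1e-8,
            length(weights) == length(means),
            length(means) == length(sds))
  set.seed(seed)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  x <- stats::rnorm(n, means[comp], sds[comp])
  v <- x
  v[v <= censor_at] <- censor_at
  list(values = v, uncensored = x, components = comp)
}
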