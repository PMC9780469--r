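# Shared fixtures, generated in code.

toy_counts <- function() {
  m <- matrix(c(0, 2, 4,
                1, 0, 3,
                5, 1, 0,
                2, 3, 1), nrow = 4, byrow = TRUE)
  dimnames(m) <- list(paste0("c", 1:4), paste0("g", 1:3))
  expression_matrix(m, space = "raw_counts")
}

# small preprocessed simulated dataset + truth, shared across tests
sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(simulation_config(n_cells = 120, n_genes = 150,
                                               seed = 11))
      m <- select_top_variance_genes(
        log_normalize(filter_low_expression(ds$counts, 0.01, 5)), 150)
      truth <- ds$truth$labels[match(m$cell_ids, ds$counts$cell_ids)]
      cache <<- list(matrix = m, truth = truth, dataset = ds)
    }
    cache
  }
})

# reduced-size pipeline configuration used for the scaled checks
fast_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, min_cells_frac = 0.01, min_genes_per_cell = 5,
         n_top_genes = 150, ae_epochs = 120, gae_epochs = 80,
         max_rounds = 5, alpha = 0),
    list(...))
  do.call(sgi_config, args)
}

two_blob_embedding <- function(n_per = 30, d = 5, sep = 6, seed = 42) {
  set.seed(seed)
  rbind(matrix(rnorm(n_per * d, 0), n_per, d),
        matrix(rnorm(n_per * d, sep), n_per, d))
}

# default-size study dataset (200 x 300, 3 clusters) with LTMG/TRS, cached
sim_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(simulation_config(seed = 1))
      cfg <- sgi_config(seed = 1, min_cells_frac = 0.01,
                        min_genes_per_cell = 10, n_top_genes = 300)
      pp <- cmd_preprocess(ds$counts, NULL, cfg)
      truth <- ds$truth$labels[match(pp$matrix$cell_ids, ds$counts$cell_ids)]
      cache <<- list(matrix = pp$matrix, trs = pp$trs, truth = truth,
                     config = cfg)
    }
    cache
  }
})
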