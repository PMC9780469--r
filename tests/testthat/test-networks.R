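test_that("feature AE loss matches closed forms and the element-wise oracle", {
  X <- matrix(1:4, 2, 2)
  expect_equal(feature_ae_loss(X, X, alpha = 0), 0)
  expect_equal(feature_ae_loss(X, X, matrix(1, 2, 2), alpha = 0.7), 0)
  expect_equal(feature_ae_loss(X, X - 1, alpha = 0), 4)
  set.seed(1)
  A <- matrix(rnorm(9), 3, 3); B <- matrix(rnorm(9), 3, 3)
  W <- matrix(rbinom(9, 1, 0.5), 3, 3)
  ref <- 0
  for (i in 1:3) for (j in 1:3) {
    ref <- ref + 0.7 * (A[i, j] - B[i, j])^2 +
      0.3 * (A[i, j] - B[i, j])^2 * W[i, j]
  }
  expect_equal(feature_ae_loss(A, B, W, alpha = 0.3), ref)
  expect_error(feature_ae_loss(A, B[1:2, ], alpha = 0), "shapes differ")
})

test_that("feature AE training is deterministic, decreasing, and recovers
          low-rank structure", {
  set.seed(2)
  X <- outer(runif(40, 1, 3), runif(30)) + matrix(rnorm(1200, 0, 0.02), 40)
  f1 <- train_feature_ae(X, NULL, dims = c(64, 16), epochs = 200, seed = 9,
                         alpha = 0)
  f2 <- train_feature_ae(X, NULL, dims = c(64, 16), epochs = 200, seed = 9,
                         alpha = 0)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$reconstructed$values, f2$reconstructed$values)
  expect_lt(tail(f1$loss_trace, 1), f1$loss_trace[1])
  mse <- mean((X - f1$reconstructed$values)^2)
  expect_lt(mse, 0.1 * var(as.vector(X)))

  # zero matrix: near-zero loss fixed point is reachable
  f0 <- train_feature_ae(matrix(0, 10, 8), NULL, dims = c(16, 4),
                         epochs = 300, seed = 1, alpha = 0)
  expect_lt(tail(f0$loss_trace, 1), 1e-4)

  # epochs = 0 returns the initialization forward pass
  fe <- train_feature_ae(X, NULL, dims = c(64, 16), epochs = 0, seed = 9,
                         alpha = 0)
  expect_length(fe$loss_trace, 0)
  expect_equal(dim(fe$embedding), c(40, 16))
})

test_that("attention coefficients are softmax-normalized over neighbors", {
  mask <- matrix(1, 3, 3)
  H <- matrix(1, 3, 2)            # identical rows -> uniform attention
  W <- matrix(rnorm(4, sd = 0.5), 2, 2)
  A <- attention_coefficients(H, W, mask)
  expect_equal(A, matrix(1 / 3, 3, 3))

  # single neighbor -> coefficient 1
  m1 <- diag(3); m1[1, 2] <- m1[2, 1] <- 1
  set.seed(3)
  H2 <- matrix(rnorm(6), 3, 2)
  A2 <- attention_coefficients(H2, W, m1)
  expect_equal(unname(rowSums(A2)), rep(1, 3), tolerance = 1e-8)
  expect_equal(A2[3, 3], 1)

  # random 4-node case against the per-row exp/normalize oracle
  set.seed(4)
  H4 <- matrix(rnorm(12), 4, 3)
  W4 <- matrix(rnorm(6), 3, 2)
  m4 <- matrix(c(1, 1, 0, 1,
                 1, 1, 1, 0,
                 0, 1, 1, 1,
                 1, 0, 1, 1), 4, 4, byrow = TRUE)
  expect_equal(attention_coefficients(H4, W4, m4),
               oracle_attention(H4, W4, m4), tolerance = 1e-10)
  expect_error(attention_coefficients(H4, W4, matrix(0, 4, 4)),
               "empty neighborhood")
})

test_that("GAT layer algebra: GCN ablation and head averaging", {
  set.seed(5)
  a <- matrix(rbinom(25, 1, 0.5), 5, 5)
  a <- pmax(a, t(a)); diag(a) <- 0
  At <- normalize_adjacency(scGraphImpute:::new_cell_graph(a))$matrix
  H <- matrix(rnorm(20), 5, 4)
  W <- matrix(rnorm(12), 4, 3)

  # heads = 0 equals the dense Atilde H W oracle (with ReLU)
  expect_equal(gat_layer(H, At, heads = 0, W = W), oracle_gcn(At, H, W),
               tolerance = 1e-10)
  # and before activation it is exactly Atilde %*% H %*% W
  expect_equal(gat_layer(H, At, heads = 0, W = W, activation = identity),
               At %*% H %*% W, tolerance = 1e-12)

  # heads = 3 equals the mean of three single-head pre-activations
  Ws <- lapply(1:3, function(i) matrix(rnorm(12, sd = 0.3), 4, 3))
  got <- gat_layer(H, At, heads = 3, W = Ws, activation = identity)
  single <- lapply(Ws, function(w)
    gat_layer(H, At, heads = 1, W = list(w), activation = identity))
  expect_equal(got, (single[[1]] + single[[2]] + single[[3]]) / 3,
               tolerance = 1e-10)

  # uniform-attention symmetry: identical features on a regular graph give
  # identical output rows
  ring <- matrix(0, 4, 4)
  for (i in 1:4) ring[i, c(i %% 4 + 1, (i + 2) %% 4 + 1)] <- 1
  Hc <- matrix(1, 4, 2)
  out <- gat_layer(Hc, normalize_adjacency(
    scGraphImpute:::new_cell_graph(ring))$matrix, heads = 1,
    W = list(matrix(rnorm(4), 2, 2)))
  expect_equal(max(apply(out, 2, function(col) diff(range(col)))), 0,
               tolerance = 1e-12)
})

test_that("GAE decoder and loss match their closed forms", {
  expect_equal(gae_decode(matrix(0, 3, 2))$values, matrix(0.5, 3, 3))
  Z <- diag(2) * 10
  d <- gae_decode(Z)$values
  expect_equal(diag(d), rep(1, 2), tolerance = 1e-6)
  expect_equal(d[1, 2], 0.5)
  set.seed(6)
  Z4 <- matrix(rnorm(8), 4, 2)
  ref <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    ref[i, j] <- 1 / (1 + exp(-sum(Z4[i, ] * Z4[j, ])))
  }
  expect_equal(gae_decode(Z4)$values, ref, tolerance = 1e-12)
  expect_equal(gae_decode(Z4)$values, t(gae_decode(Z4)$values))

  expect_equal(gae_loss(matrix(1, 2, 2), matrix(0.5, 2, 2)), log(2))
  expect_lt(gae_loss(diag(2), pmin(pmax(diag(2), 1e-7), 1 - 1e-7)), 1e-6)
  set.seed(7)
  A <- matrix(rbinom(9, 1, 0.5), 3, 3)
  P <- matrix(runif(9, 0.05, 0.95), 3, 3)
  ref <- 0
  for (i in 1:3) for (j in 1:3) {
    ref <- ref - (A[i, j] * log(P[i, j]) +
                    (1 - A[i, j]) * log(1 - P[i, j])) / 9
  }
  expect_equal(gae_loss(A, P), ref, tolerance = 1e-12)
})

test_that("GAE training recovers planted two-blob structure", {
  X <- two_blob_embedding()
  g <- build_knn_graph(X, 8)
  ge <- train_gae(g, X, heads = 3, epochs = 150, seed = 7)
  blob <- rep(1:2, each = 30)
  within <- outer(blob, blob, `==`) & g$adjacency > 0
  expect_gte(mean(ge$Ahat[within] > 0.5), 0.9)
  expect_lt(tail(ge$loss_trace, 1), ge$loss_trace[1])
  # attention rows sum to one over neighborhoods
  for (A_att in ge$attention) {
    expect_equal(unname(rowSums(A_att)), rep(1, 60), tolerance = 1e-8)
  }

  # epochs = 0 returns the initialization forward pass, deterministically
  z0a <- train_gae(g, X, heads = 1, epochs = 0, seed = 3)$Z
  z0b <- train_gae(g, X, heads = 1, epochs = 0, seed = 3)$Z
  expect_identical(z0a, z0b)

  # ablation API: heads = 0 and heads = 3 both run
  expect_s3_class(train_gae(g, X, heads = 0, epochs = 5, seed = 1),
                  "graph_embedding")
})

test_that("cluster autoencoders reassemble rows in original order", {
  set.seed(8)
  X <- matrix(runif(40 * 12), 40, 12)
  lab <- rep(c(0L, 1L), each = 20)
  out <- train_cluster_ae(X, lab, NULL, dims = c(16, 4), epochs = 50,
                          seed = 1, alpha = 0, min_cluster_size = 5)
  # permuting the cells and training per cluster gives the same rows back
  perm <- sample(40)
  out_p <- train_cluster_ae(X[perm, ], lab[perm], NULL, dims = c(16, 4),
                            epochs = 50, seed = 1, alpha = 0,
                            min_cluster_size = 5)
  expect_equal(out_p$values, out$values[perm, ], tolerance = 1e-10)

  # a single cluster is one feature AE on the whole matrix
  one <- train_cluster_ae(X, rep(0L, 40), NULL, dims = c(16, 4), epochs = 50,
                          seed = 1, alpha = 0, min_cluster_size = 5)
  fa <- train_dense_ae(X, dims = c(16, 4), epochs = 50, seed = 2)
  expect_equal(one$values, fa$Xhat, tolerance = 1e-10)

  # tiny clusters pass through untrained
  lab2 <- c(rep(0L, 38), 1L, 1L)
  expect_message(
    pt <- train_cluster_ae(X, lab2, NULL, dims = c(16, 4), epochs = 20,
                           seed = 1, alpha = 0, min_cluster_size = 5),
    "passed through")
  expect_equal(pt$values[39:40, ], X[39:40, ])
})

test_that("imputation loss decomposes into its five oracle terms", {
  set.seed(9)
  X <- matrix(runif(12), 4, 3)
  Xh <- X + matrix(rnorm(12, 0, 0.3), 4, 3)
  W <- matrix(rbinom(12, 1, 0.5), 4, 3)
  A <- matrix(rbinom(16, 1, 0.5), 4, 4); A <- pmax(A, t(A)); diag(A) <- 0
  B <- same_type_matrix(c(0, 0, 1, 1))

  expect_equal(as.numeric(imputation_loss(X, X, W, A, B, beta = 0)), 0)
  # term isolation: alpha = gamma = 0, beta = 1
  l <- imputation_loss(X, Xh, NULL, A, B, alpha = 0, beta = 1,
                       gamma1 = 0, gamma2 = 0, weights_l1 = 2.5)
  expect_equal(as.numeric(l), sum((X - Xh)^2) + 2.5)

  full <- imputation_loss(X, Xh, W, A, B, alpha = 0.4, beta = 0.2,
                          gamma1 = 0.3, gamma2 = 0.6, weights_l1 = 1.1)
  ref <- 0.6 * sum((X - Xh)^2) + 0.4 * sum((X - Xh)^2 * W) + 0.2 * 1.1
  for (i in 1:4) for (j in 1:4) {
    ref <- ref + 0.3 * A[i, j] * sum((X[i, ] - Xh[i, ])^2) +
      0.6 * B[i, j] * sum((X[i, ] - Xh[i, ])^2)
  }
  expect_equal(as.numeric(full), ref)
  expect_error(imputation_loss(X, Xh, W, A, matrix(2, 4, 4)), "0/1")
})

test_that("imputation AE recovers corrupted low-rank entries and responds
          to L1", {
  set.seed(10)
  X <- outer(runif(40, 1, 2), runif(30, 0.5, 2)) +
    matrix(rnorm(1200, 0, 0.05), 40)
  X[X < 0] <- 0
  corr <- apply_synthetic_dropout(X, 0.1, seed = 3)
  A <- build_knn_graph(X, 5)$adjacency
  B <- same_type_matrix(rep(0L, 40))
  fit <- train_imputation_ae(corr$corrupted, A, B, NULL, dims = c(64, 16),
                             epochs = 250, seed = 4, alpha = 0, beta = 0.1)
  imputed <- impute_zeros(corr$corrupted, fit$reconstructed)
  m_imp <- imputation_metrics(X, imputed, corr$mask)
  m_cor <- imputation_metrics(X, corr$corrupted, corr$mask)
  expect_gt(m_imp$cosine, ifelse(is.na(m_cor$cosine), 0, m_cor$cosine))
  expect_lt(m_imp$rmse, m_cor$rmse)

  # stronger L1 shrinks the weight norm, same seed
  f0 <- train_imputation_ae(X, A, B, NULL, dims = c(32, 8), epochs = 100,
                            seed = 5, alpha = 0, beta = 0)
  f1 <- train_imputation_ae(X, A, B, NULL, dims = c(32, 8), epochs = 100,
                            seed = 5, alpha = 0, beta = 1)
  expect_lt(f1$weights_l1, f0$weights_l1)

  # determinism
  f2 <- train_imputation_ae(X, A, B, NULL, dims = c(32, 8), epochs = 100,
                            seed = 5, alpha = 0, beta = 0)
  expect_identical(f0$reconstructed$values, f2$reconstructed$values)
})

test_that("training losses never increase from first to final epoch on
          fixture inputs", {
  set.seed(11)
  X <- matrix(runif(200), 20, 10)
  f <- train_dense_ae(X, dims = c(16, 4), epochs = 100, seed = 1)
  expect_lte(tail(f$loss_trace, 1), f$loss_trace[1])
  g <- build_knn_graph(matrix(rnorm(40), 20, 2), 4)
  ge <- train_gae(g, X, heads = 1, epochs = 60, seed = 2)
  expect_lte(tail(ge$loss_trace, 1), ge$loss_trace[1])
})
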