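test_that("synthetic dropout flips exactly the requested support entries", {
  set.seed(1)
  X <- matrix(rpois(100, 2), 10, 10)
  nnz <- sum(X != 0)
  out <- apply_synthetic_dropout(X, 0.1, seed = 5)
  expect_identical(nrow(out$mask$flipped_indices),
                   as.integer(round(0.1 * nnz)))
  expect_true(all(X[out$mask$flipped_indices] != 0))
  expect_true(all(out$corrupted[out$mask$flipped_indices] == 0))
  # untouched elsewhere
  touched <- matrix(FALSE, 10, 10)
  touched[out$mask$flipped_indices] <- TRUE
  expect_equal(out$corrupted[!touched], X[!touched])
  # determinism
  out2 <- apply_synthetic_dropout(X, 0.1, seed = 5)
  expect_identical(out$mask$flipped_indices, out2$mask$flipped_indices)
  expect_error(apply_synthetic_dropout(diag(2), 0.1), "nothing to flip")
})

test_that("imputation metrics hit their fixed points and the scalar oracle", {
  set.seed(2)
  X <- matrix(runif(80, 0, 4), 10, 8)
  p <- imputation_metrics(X, X, scope = "all")
  expect_equal(p$l1_median, 0)
  expect_equal(p$l1_mean, 0)
  expect_equal(p$cosine, 1)
  expect_equal(p$rmse, 0)

  # parallel vectors have cosine 1
  a <- matrix(c(1, 2), 1, 2)
  expect_equal(imputation_metrics(a, 2 * a, scope = "all")$cosine, 1)

  Y <- X + matrix(rnorm(80, 0, 0.5), 10, 8)
  sel <- matrix(runif(80) < 0.4, 10, 8)
  idx <- which(sel, arr.ind = TRUE)
  colnames(idx) <- c("cell", "gene")
  mask <- structure(list(flipped_indices = idx, rate = NA, seed = NA),
                    class = "dropout_mask")
  got <- imputation_metrics(X, Y, mask, scope = "masked_only")
  ref <- oracle_imputation(X, Y, sel)
  for (f in names(ref)) expect_equal(got[[f]], ref[[f]], tolerance = 1e-12)
})

test_that("ARI matches hand pair counting and relabeling invariance", {
  expect_equal(ari(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_equal(ari(c(0, 1, 2), c(2, 0, 1)), 1)  # singletons everywhere
  expect_error(ari(1, 1), "at least 2")
})

test_that("entropy-based scores satisfy their definitional corners", {
  s <- information_scores(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(unname(unlist(s)), rep(1, 5))
  # one cluster holding two classes: complete but not homogeneous
  s2 <- information_scores(c(0, 1), c(0, 0))
  expect_equal(s2$cs, 1)
  expect_equal(s2$hs, 0)
})

test_that("Fowlkes-Mallows agrees with exhaustive pair enumeration", {
  expect_equal(fowlkes_mallows(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  # crossed labeling: no pair is together in both partitions
  expect_equal(oracle_fms(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(fowlkes_mallows(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  set.seed(3)
  a <- sample(0:2, 200, replace = TRUE)
  b <- sample(0:3, 200, replace = TRUE)
  expect_equal(fowlkes_mallows(a, b), oracle_fms(a, b), tolerance = 1e-12)
  # independent labelings sit near the chance level sqrt(Pa * Pb) / P
  expect_lt(fowlkes_mallows(a, b), 0.6)
})

test_that("silhouette and Davies-Bouldin match exhaustive computation", {
  # two tight, far-apart blobs
  set.seed(4)
  X <- rbind(matrix(rnorm(8, 0, 0.1), 4, 2), matrix(rnorm(8, 10, 0.1), 4, 2))
  lab <- rep(1:2, each = 4)
  g <- geometry_scores(X, lab)
  expect_gt(g$silhouette, 0.9)
  expect_equal(g$silhouette, oracle_silhouette(X, lab), tolerance = 1e-12)
  expect_equal(g$dbs, oracle_dbs(X, lab), tolerance = 1e-12)

  # hand-placed 1-D points {0, 1, 10, 11}
  X1 <- matrix(c(0, 1, 10, 11), 4, 1)
  l1 <- c(0, 0, 1, 1)
  expect_equal(geometry_scores(X1, l1)$silhouette,
               oracle_silhouette(X1, l1), tolerance = 1e-12)

  # all points identical: a = b = 0 -> silhouette 0
  expect_equal(geometry_scores(matrix(1, 6, 2), rep(1:2, 3))$silhouette, 0)
  expect_error(geometry_scores(X, rep(1, 8)), "at least 2")
})

test_that("clustering metrics are invariant under label permutation", {
  set.seed(5)
  for (r in 1:10) {
    a <- sample(0:2, 25, replace = TRUE)
    b <- sample(0:3, 25, replace = TRUE)
    pa <- sample(0:2)[a + 1]
    pb <- sample(0:3)[b + 1]
    expect_equal(ari(a, b), ari(pa, pb), tolerance = 1e-12)
    expect_equal(fowlkes_mallows(a, b), fowlkes_mallows(pa, pb),
                 tolerance = 1e-12)
    expect_equal(information_scores(a, b), information_scores(pa, pb),
                 tolerance = 1e-12)
  }
})

test_that("chance-adjusted scores are centered for independent labelings", {
  set.seed(6)
  aris <- amis <- numeric(200)
  for (r in 1:200) {
    a <- sample(0:2, 40, replace = TRUE)
    b <- sample(0:2, 40, replace = TRUE)
    aris[r] <- ari(a, b)
    amis[r] <- information_scores(a, b)$ami
  }
  expect_lt(abs(mean(aris)), 0.05)
  expect_lt(abs(mean(amis)), 0.05)
})

test_that("information scores match the from-scratch contingency oracle", {
  set.seed(7)
  for (r in 1:10) {
    a <- sample(0:2, 30, replace = TRUE)
    b <- sample(0:3, 30, replace = TRUE)
    got <- information_scores(a, b)
    ref <- oracle_entropy_scores(a, b)
    expect_equal(got$nmi, ref$nmi, tolerance = 1e-12)
    expect_equal(got$cs, ref$cs, tolerance = 1e-12)
    expect_equal(got$hs, ref$hs, tolerance = 1e-12)
    expect_equal(got$vms, ref$vms, tolerance = 1e-12)
  }
})
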