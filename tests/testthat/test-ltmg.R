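test_that("single-component fit recovers sample moments without censoring", {
  s <- generate_censored_mixture(2000, 1, 3, 1, censor_at = -Inf, seed = 2)
  f <- fit_ltmg_gene(s$values, k = 1, trunc_threshold = -10)
  expect_lt(abs(f$means - mean(s$values)), 0.1)
  expect_lt(abs(f$sds - sd(s$values)), 0.1)
  # exact MLE for k = 1: mean and sqrt of the biased variance
  expect_equal(f$means, mean(s$values), tolerance = 1e-4)
  expect_equal(f$sds, sqrt(mean((s$values - mean(s$values))^2)),
               tolerance = 1e-3)
})

test_that("censored two-component EM recovers the generating parameters", {
  s <- generate_censored_mixture(4000, c(0.5, 0.5), c(1, 4), c(0.3, 0.5),
                                 censor_at = 0, seed = 3)
  f <- fit_ltmg_gene(s$values, k = 2, trunc_threshold = 0)
  expect_lt(max(abs(f$means - c(1, 4))), 0.2)
  expect_lt(max(abs(f$sds - c(0.3, 0.5))), 0.2)
  expect_equal(sum(f$mixing_probs), 1, tolerance = 1e-8)
  expect_true(all(diff(f$means) > 0))
})

test_that("degenerate inputs are flagged or rejected", {
  # everything censored: single-component degenerate fit
  f <- fit_ltmg_gene(rep(0, 50), k = 1, trunc_threshold = 0)
  expect_true(f$degenerate)
  # k larger than the distinct uncensored values
  x <- c(rep(0, 20), rep(2.5, 10))
  expect_error(fit_ltmg_gene(x, k = 3), "degenerate")
  expect_error(fit_ltmg_gene(1:5, k = 1), "at least 10")
})

test_that("BIC selects the generating modality", {
  uni <- generate_censored_mixture(1500, 1, 2, 0.5, seed = 4)
  expect_identical(select_components(uni$values, k_max = 3,
                                     trunc_threshold = -10)$n_components, 1L)
  bi <- generate_censored_mixture(4000, c(0.5, 0.5), c(0, 5), c(1, 1),
                                  seed = 5)
  expect_identical(select_components(bi$values, k_max = 3,
                                     trunc_threshold = -10)$n_components, 2L)
  # k_max = 1 falls back to the plain fit
  f1 <- select_components(bi$values, k_max = 1, trunc_threshold = -10)
  f2 <- fit_ltmg_gene(bi$values, k = 1, trunc_threshold = -10)
  expect_equal(f1$loglik, f2$loglik)
})

test_that("EM log-likelihood is non-decreasing on a panel of fixture genes", {
  set.seed(6)
  for (r in 1:12) {
    k_true <- sample(1:2, 1)
    w <- if (k_true == 1) 1 else c(0.4, 0.6)
    s <- generate_censored_mixture(300, w, sort(runif(k_true, 0, 4)),
                                   runif(k_true, 0.3, 1),
                                   censor_at = 0, seed = 100 + r)
    f <- fit_ltmg_gene(s$values, k = sample(1:2, 1), trunc_threshold = 0)
    if (length(f$loglik_trace) > 1) {
      expect_true(all(diff(f$loglik_trace) >= -1e-8 *
                        pmax(1, abs(f$loglik_trace[-1]))))
    }
  }
})

test_that("censoring below the data minimum reduces to a standard mixture", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  s <- generate_censored_mixture(1200, c(0.4, 0.6), c(1, 5), c(0.5, 0.8),
                                 seed = 7)
  f <- fit_ltmg_gene(s$values, k = 2, trunc_threshold = min(s$values) - 1)
  mc <- Mclust(s$values, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(f$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(f$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("TRS labels maximize the component posterior with low tie-break", {
  m <- expression_matrix(matrix(c(0, 10, 5, 0.2), 4, 1),
                         gene_ids = "g", space = "log_normalized")
  fit <- structure(list(n_components = 2L, mixing_probs = c(0.5, 0.5),
                        means = c(0, 10), sds = c(1, 1),
                        trunc_threshold = 0, loglik = 0, bic = 0,
                        n_obs = 4L, n_censored = 0L, degenerate = FALSE),
                   class = "ltmg_fit")
  trs <- assign_trs(m, list(g = fit))
  expect_identical(as.integer(trs$labels[, 1]), c(1L, 2L, 1L, 1L))
  # x = 5 is the exact equal-posterior point -> label 1 by tie-break
  expect_identical(trs$labels[3, 1], 1L)

  # single-component gene: everything labeled 1
  f1 <- fit_ltmg_gene(rnorm(50, 3), k = 1, trunc_threshold = -10)
  m1 <- expression_matrix(matrix(rnorm(50, 3), 50, 1),
                          space = "log_normalized")
  expect_true(all(assign_trs(m1, list(f1))$labels == 1L))

  expect_error(assign_trs(m, list(h = fit)), "missing LTMG fit")
})

test_that("TRS labels are invariant to component relabeling via mean sort", {
  set.seed(8)
  x <- c(rnorm(100, 0, 0.5), rnorm(100, 4, 0.5))
  f <- fit_ltmg_gene(x, k = 2, trunc_threshold = -10)
  m <- expression_matrix(matrix(x, ncol = 1), space = "log_normalized")
  lab <- assign_trs(m, list(f))$labels[, 1]
  # component 1 is the lower-mean one after sorting
  expect_true(mean(x[lab == 1]) < mean(x[lab == 2]))
  w <- trs_weight(assign_trs(m, list(f)), "binary")
  expect_setequal(unique(as.vector(w)), c(0, 1))
  expect_equal(as.vector(w), as.numeric(lab > 1))
})
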