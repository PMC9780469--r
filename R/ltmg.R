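#' Left-truncated Gaussian mixture (LTMG) per-gene model
#'
#' Expression of one gene across cells is modeled as a k-component Gaussian
#' mixture in which observations at or below a truncation threshold (Zcut,
#' by default 0 in log space, i.e. observed zeros) are treated as
#' left-censored: their likelihood contribution is the mixture CDF mass
#' below Zcut. Parameters are estimated by expectation-maximization with the
#' standard censored-data E-step (truncated-Gaussian conditional moments).
#'
#' @name ltmg
NULL

# log Mills-type ratio h = phi(z)/Phi(z), computed in log space for stability
.mills_lower <- function(z) {
  exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
}

.logsumexp_rows <- function(lm) {
  mx <- apply(lm, 1, max)
  mx + log(rowSums(exp(lm - mx)))
}

#' Fit the LTMG model to one gene
#'
#' @param x numeric vector of (log-normalized) expression values across cells.
#' @param k number of mixture components.
#' @param trunc_threshold censoring threshold Zcut; values `<=` it are
#'   treated as left-censored (default 0).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param sd_floor lower bound on component standard deviations.
#' @return An object of class `ltmg_fit`: `n_components`, `mixing_probs`,
#'   `means`, `sds` (components sorted by ascending mean), `trunc_threshold`,
#'   `loglik`, `bic`, `loglik_trace`, `n_obs` (uncensored count M),
#'   `n_censored`, `converged`, `degenerate`.
#' @export
fit_ltmg_gene <- function(x, k = 1, trunc_threshold = 0, tol = 1e-6,
                          max_iter = 200, sd_floor = 1e-3) {
  stopifnot(is.numeric(x), k >= 1)
  if (length(x) < 10) stop("need at least 10 observations, got ", length(x))
  zcut <- trunc_threshold
  cens <- x <= zcut
  xo <- x[!cens]
  m_obs <- length(xo)
  n_cens <- sum(cens)
  if (m_obs == 0) {
    return(structure(list(n_components = 1L, mixing_probs = 1,
                          means = zcut, sds = sd_floor,
                          trunc_threshold = zcut, loglik = NA_real_,
                          bic = NA_real_, loglik_trace = numeric(0),
                          n_obs = 0L, n_censored = n_cens,
                          converged = FALSE, degenerate = TRUE),
                     class = "ltmg_fit"))
  }
  if (k > length(unique(xo)))
    stop("degenerate model: k = ", k, " exceeds the ", length(unique(xo)),
         " distinct uncensored value(s)")

  # quantile-spaced means, pooled sd, uniform mixing
  mu <- as.numeric(stats::quantile(xo, probs = (seq_len(k)) / (k + 1),
                                   names = FALSE, type = 7))
  sg <- rep(max(stats::sd(xo), sd_floor), k)
  if (k == 1) sg <- max(sqrt(mean((xo - mu)^2)), sd_floor)
  al <- rep(1 / k, k)

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # --- E-step ---
    lp_obs <- vapply(seq_len(k), function(i) {
      log(al[i]) + stats::dnorm(xo, mu[i], sg[i], log = TRUE)
    }, numeric(m_obs))
    lp_obs <- matrix(lp_obs, nrow = m_obs)
    lse_obs <- .logsumexp_rows(lp_obs)
    r_obs <- exp(lp_obs - lse_obs)
    ll <- sum(lse_obs)
    if (n_cens > 0) {
      lp_c <- log(al) + stats::pnorm(zcut, mu, sg, log.p = TRUE)
      lse_c <- max(lp_c) + log(sum(exp(lp_c - max(lp_c))))
      r_cens <- exp(lp_c - lse_c)
      ll <- ll + n_cens * lse_c
    } else {
      r_cens <- rep(0, k)
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * (abs(ll_prev) + tol)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    # --- M-step (censored-data sufficient statistics) ---
    nk <- colSums(r_obs) + n_cens * r_cens
    nk <- pmax(nk, 1e-12)
    if (n_cens > 0) {
      z <- (zcut - mu) / sg
      h <- .mills_lower(z)
      cm <- mu - sg * h                        # E[X | X <= zcut, comp]
      cv <- pmax(sg^2 * (1 - z * h - h^2), 1e-12)
    } else {
      cm <- mu
      cv <- rep(0, k)
    }
    mu_new <- (colSums(r_obs * xo) + n_cens * r_cens * cm) / nk
    var_new <- (colSums(r_obs * (xo - rep(mu_new, each = m_obs))^2) +
                  n_cens * r_cens * (cv + (cm - mu_new)^2)) / nk
    al <- nk / (m_obs + n_cens)
    mu <- mu_new
    sg <- pmax(sqrt(var_new), sd_floor)
  }

  ord <- order(mu)
  p_free <- 3 * k - 1
  structure(list(n_components = as.integer(k), mixing_probs = al[ord],
                 means = mu[ord], sds = sg[ord], trunc_threshold = zcut,
                 loglik = ll, bic = -2 * ll + p_free * log(m_obs),
                 loglik_trace = ll_trace, n_obs = as.integer(m_obs),
                 n_censored = as.integer(n_cens), converged = converged,
                 degenerate = FALSE),
            class = "ltmg_fit")
}

#' @export
print.ltmg_fit <- function(x, ...) {
  cat("<ltmg_fit> k =", x$n_components, if (x$degenerate) "(degenerate)",
      "\n  alpha:", signif(x$mixing_probs, 3),
      "\n  mu:   ", signif(x$means, 4),
      "\n  sigma:", signif(x$sds, 4),
      "\n  loglik:", signif(x$loglik, 6), " BIC:", signif(x$bic, 6), "\n")
  invisible(x)
}

#' Select the number of LTMG components by BIC
#'
#' Fits `k = 1..k_max` and returns the fit minimizing
#' `BIC = -2 loglik + (3k - 1) log(M)` where M is the number of uncensored
#' observations.
#'
#' @inheritParams fit_ltmg_gene
#' @param k_max largest component count to try (default 5).
#' @return The BIC-optimal `ltmg_fit`.
#' @export
select_components <- function(x, k_max = 5, trunc_threshold = 0, tol = 1e-6,
                              max_iter = 200, sd_floor = 1e-3) {
  stopifnot(k_max >= 1)
  fits <- vector("list", k_max)
  errs <- character(0)
  for (k in seq_len(k_max)) {
    fits[[k]] <- tryCatch(
      fit_ltmg_gene(x, k, trunc_threshold, tol, max_iter, sd_floor),
      error = function(e) {
        errs <<- c(errs, conditionMessage(e))
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all component counts failed: ",
                     paste(unique(errs), collapse = "; "))
  bics <- vapply(fits[ok], function(f) {
    if (is.na(f$bic)) Inf else f$bic
  }, numeric(1))
  fits[ok][[which.min(bics)]]
}

#' Fit LTMG models for every gene of a matrix
#'
#' @param m a log-normalized [expression_matrix()].
#' @param k_max per-gene maximum component count for BIC selection.
#' @inheritParams fit_ltmg_gene
#' @return Named list of `ltmg_fit` objects, one per gene.
#' @export
fit_ltmg <- function(m, k_max = 5, trunc_threshold = 0, tol = 1e-6,
                     max_iter = 200, sd_floor = 1e-3) {
  stopifnot(inherits(m, "expression_matrix"))
  fits <- lapply(seq_len(ncol(m$values)), function(g) {
    select_components(m$values[, g], k_max, trunc_threshold, tol, max_iter,
                      sd_floor)
  })
  names(fits) <- m$gene_ids
  fits
}

#' Discretize expression into transcriptional regulatory signal (TRS) labels
#'
#' Each entry is labeled with the mixture component maximizing the posterior
#' `alpha_i * N(x; mu_i, sigma_i)` under its gene's fit; ties go to the
#' lower-mean component (components are sorted by ascending mean).
#'
#' @param m an [expression_matrix()].
#' @param fits a list of `ltmg_fit` objects, one per gene of `m` (named or
#'   positional).
#' @return An object of class `trs_matrix`: integer `labels` (N x G, entries
#'   in 1..k per gene) plus `gene_components`.
#' @export
assign_trs <- function(m, fits) {
  stopifnot(inherits(m, "expression_matrix"))
  g <- ncol(m$values)
  if (!is.null(names(fits))) {
    missing <- setdiff(m$gene_ids, names(fits))
    if (length(missing))
      stop("missing LTMG fit for gene(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    fits <- fits[m$gene_ids]
  } else if (length(fits) != g) {
    stop("need one fit per gene: got ", length(fits), " fits for ", g,
         " genes")
  }
  labels <- matrix(1L, nrow(m$values), g,
                   dimnames = dimnames(m$values))
  for (j in seq_len(g)) {
    f <- fits[[j]]
    k <- f$n_components
    if (k == 1) next
    lp <- vapply(seq_len(k), function(i) {
      log(f$mixing_probs[i]) +
        stats::dnorm(m$values[, j], f$means[i], f$sds[i], log = TRUE)
    }, numeric(nrow(m$values)))
    labels[, j] <- max.col(matrix(lp, nrow = nrow(m$values)),
                           ties.method = "first")
  }
  structure(list(labels = labels,
                 gene_components = vapply(fits, `[[`, integer(1),
                                          "n_components")),
            class = "trs_matrix")
}

#' TRS loss-weight matrix
#'
#' Converts TRS labels into the per-entry weight used by the regularized
#' reconstruction losses. `"binary"` (default): weight 1 where the label
#' exceeds 1 (the entry sits in an expressed/regulated component), else 0;
#' `"label"`: the raw integer label; `"none"`: all ones.
#'
#' @param trs a `trs_matrix` (or NULL, returning NULL).
#' @param mode weighting mode.
#' @return Numeric matrix of weights, or NULL.
#' @export
trs_weight <- function(trs, mode = c("binary", "label", "none")) {
  mode <- match.arg(mode)
  if (is.null(trs)) return(NULL)
  stopifnot(inherits(trs, "trs_matrix"))
  switch(mode,
         binary = (trs$labels > 1) * 1.0,
         label = trs$labels * 1.0,
         none = array(1.0, dim(trs$labels), dimnames = dimnames(trs$labels)))
}

#' Export per-gene LTMG fit parameters as a data frame
#'
#' @param fits list of `ltmg_fit` objects (as from [fit_ltmg()]).
#' @return data.frame with one row per gene: k, BIC, loglik, and
#'   slash-separated alpha/mu/sigma lists.
#' @export
ltmg_fit_table <- function(fits) {
  data.frame(
    gene = if (is.null(names(fits))) seq_along(fits) else names(fits),
    k = vapply(fits, `[[`, integer(1), "n_components"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    alpha = vapply(fits, function(f)
      paste(signif(f$mixing_probs, 6), collapse = "/"), character(1)),
    mu = vapply(fits, function(f)
      paste(signif(f$means, 6), collapse = "/"), character(1)),
    sigma = vapply(fits, function(f)
      paste(signif(f$sds, 6), collapse = "/"), character(1)),
    row.names = NULL)
}
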