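# Variational-Bayes Gaussian mixture (CAVI for the Dirichlet +
# Gaussian-Wishart conjugate model).  Over-provision K components with a
# sparse weight-concentration prior and let the evidence prune the
# surplus; the effective component count is then data-driven.

log_dmvnorm <- function(X, mu, Sigma) {
  d <- ncol(X)
  ch <- chol(Sigma)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

vb_gmm_cavi <- function(X, K, alpha0, beta0, m0, nu0, W0inv,
                        r_init, tol, max_iter, reg) {
  n <- nrow(X); D <- ncol(X)
  r <- r_init
  ln2pi <- log(2 * pi)
  elbo_old <- -Inf
  for (iter in seq_len(max_iter)) {
    Nk <- pmax(colSums(r), 1e-10)
    xbar <- t(r) %*% X / Nk                       # K x D
    alpha <- alpha0 + Nk
    beta <- beta0 + Nk
    nu <- nu0 + Nk
    m <- (beta0 * matrix(m0, K, D, byrow = TRUE) + Nk * xbar) / beta
    Winv <- vector("list", K)
    for (k in seq_len(K)) {
      xc <- sweep(X, 2L, xbar[k, ])
      Sk <- crossprod(xc * r[, k], xc)            # Nk * S_k
      dk <- xbar[k, ] - m0
      Winv[[k]] <- W0inv + Sk +
        (beta0 * Nk[k] / (beta0 + Nk[k])) * tcrossprod(dk) +
        diag(reg, D)
    }
    # expectations for the E step
    eln_pi <- digamma(alpha) - digamma(sum(alpha))
    eln_lam <- numeric(K)
    maha <- matrix(0, n, K)
    logdetWinv <- numeric(K)
    for (k in seq_len(K)) {
      ch <- chol(Winv[[k]])
      logdetWinv[k] <- 2 * sum(log(diag(ch)))
      eln_lam[k] <- sum(digamma((nu[k] + 1 - seq_len(D)) / 2)) +
        D * log(2) - logdetWinv[k]
      z <- forwardsolve(t(ch), t(X) - m[k, ])     # solves Winv^{1/2} z = x-m
      maha[, k] <- nu[k] * colSums(z^2) + D / beta[k]
    }
    lrho <- sweep(-0.5 * maha, 2L,
                  eln_pi + 0.5 * eln_lam - 0.5 * D * ln2pi, "+")
    mx <- apply(lrho, 1L, max)
    lse <- mx + log(rowSums(exp(lrho - mx)))
    r <- exp(lrho - lse)
    elbo <- vb_gmm_elbo(X, lse, alpha, alpha0, beta, beta0, m, m0,
                        nu, nu0, Winv, W0inv, eln_pi)
    if (is.finite(elbo) && abs(elbo - elbo_old) < tol * abs(elbo_old + 1))
      break
    elbo_old <- elbo
  }
  list(alpha = alpha, beta = beta, m = m, nu = nu, Winv = Winv,
       r = r, elbo = elbo, Nk = Nk)
}

# Exact variational lower bound evaluated right after the E step, where
# it collapses to  sum_n lse_n - KL(q(pi)||p(pi))
#                  - sum_k KL(q(mu_k, Lambda_k)||p(mu_k, Lambda_k)).
vb_gmm_elbo <- function(X, lse, alpha, alpha0, beta, beta0, m, m0,
                        nu, nu0, Winv, W0inv, eln_pi) {
  K <- length(alpha); D <- ncol(X)
  lB <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  kl_dir <- lB(rep(alpha0, K)) - lB(alpha) + sum((alpha - alpha0) * eln_pi)
  logdetW0inv <- 2 * sum(log(diag(chol(W0inv))))
  psi_D <- function(a) sum(digamma(a + (1 - seq_len(D)) / 2))
  lmvgamma <- function(a) D * (D - 1) / 4 * log(pi) +
    sum(lgamma(a + (1 - seq_len(D)) / 2))
  kl_gw <- 0
  for (k in seq_len(K)) {
    Wk <- chol2inv(chol(Winv[[k]]))
    logdetWk <- -2 * sum(log(diag(chol(Winv[[k]]))))
    # KL( W(nu_k, W_k) || W(nu0, W0) ), W0 = W0inv^{-1}
    kl_wish <- -nu0 / 2 * (logdetW0inv + logdetWk) +
      nu[k] / 2 * (sum(W0inv * Wk) - D) +
      lmvgamma(nu0 / 2) - lmvgamma(nu[k] / 2) +
      (nu[k] - nu0) / 2 * (psi_D(nu[k] / 2) + D * log(2) + logdetWk)
    dm <- m[k, ] - m0
    kl_gauss <- 0.5 * (D * (beta0 / beta[k] - 1 - log(beta0 / beta[k])) +
                       beta0 * nu[k] * drop(t(dm) %*% Wk %*% dm))
    kl_gw <- kl_gw + kl_wish + kl_gauss
  }
  sum(lse) - kl_dir - kl_gw
}

#' Fit a variational-Bayes Gaussian mixture to one cell's PCA scores
#'
#' Up to `max_K` components with a sparse Dirichlet weight prior
#' (concentration `1/max_K`); surplus components collapse to negligible
#' weight, yielding an automatic effective component count.  The
#' returned density uses posterior-mean parameters.
#'
#' @param scores numeric matrix of 3-D points (rows).
#' @param max_K maximum number of components (default 20).
#' @param seed integer seed (3 restarts with derived seeds; the highest
#'   variational bound wins).
#' @param n_restarts number of random restarts.
#' @param tol relative convergence tolerance of the bound.
#' @param reg covariance regularization added to each scale update.
#' @return object of class `cell_gmm`: `weights`, `means` (K x D),
#'   `covs` (list of D x D), `effective_K`, `elbo`.
#' @export
fit_cell_gmm <- function(scores, max_K = 20L, seed = 1L,
                         n_restarts = 3L, tol = 1e-5, reg = 1e-6) {
  X <- as.matrix(scores)
  n <- nrow(X); D <- ncol(X)
  if (n < 10L) {
    warning("fewer than 10 points: single-Gaussian fallback")
    cv <- if (n >= 2L) stats::cov(X) else diag(1, D)
    cv <- cv + diag(reg, D)
    return(structure(list(weights = 1, means = matrix(colMeans(X), 1L),
                          covs = list(cv), effective_K = 1L, elbo = NA_real_),
                     class = "cell_gmm"))
  }
  # over-provisioning beyond ~n/10 components just spreads prior mass:
  # VB needs several points per surviving component to prune sensibly
  K <- as.integer(max(1L, min(max_K, n %/% 10L)))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds < 1e-12))
    warning("rank-deficient scores: covariance regularization applied")
  alpha0 <- 1 / K
  beta0 <- 1
  m0 <- colMeans(X)
  W0inv <- diag(pmax(sds^2, 1e-8), D)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, rs))
    km <- tryCatch(stats::kmeans(X, centers = K, nstart = 1L,
                                 iter.max = 30L),
                   error = function(e) NULL)
    assign_ <- if (is.null(km)) sample.int(K, n, replace = TRUE) else km$cluster
    r0 <- matrix(1e-8, n, K)
    r0[cbind(seq_len(n), assign_)] <- 1
    r0 <- r0 / rowSums(r0)
    fit <- vb_gmm_cavi(X, K, alpha0, beta0, m0, D + 2, W0inv,
                       r0, tol, 200L, reg)
    if (is.null(best) || (is.finite(fit$elbo) && fit$elbo > best$elbo))
      best <- fit
  }
  w <- best$alpha / sum(best$alpha)
  covs <- lapply(seq_len(K), function(k)
    best$Winv[[k]] / (best$nu[k] - D - 1))
  keep <- w >= 1e-3
  eff_K <- sum(keep)
  # drop pruned components and renormalize for the reported density
  w <- w[keep] / sum(w[keep])
  structure(list(weights = w,
                 means = best$m[keep, , drop = FALSE],
                 covs = covs[keep],
                 effective_K = as.integer(eff_K),
                 elbo = best$elbo),
            class = "cell_gmm")
}

#' Log-density of a fitted cell mixture at 3-D points
#' @param gmm a `cell_gmm`.
#' @param y numeric matrix of points (rows) or a single point.
#' @return numeric vector of log-densities (finite for finite `y`).
#' @export
gmm_log_density <- function(gmm, y) {
  y <- if (is.null(dim(y))) matrix(y, nrow = 1L) else as.matrix(y)
  K <- length(gmm$weights)
  lp <- matrix(0, nrow(y), K)
  for (k in seq_len(K))
    lp[, k] <- log(gmm$weights[k]) +
      log_dmvnorm(y, gmm$means[k, ], gmm$covs[[k]])
  apply(lp, 1L, logsumexp)
}

#' Draw points from a fitted cell mixture
#' @param gmm a `cell_gmm`.
#' @param n number of points.
#' @return n x D matrix.
#' @export
gmm_sample <- function(gmm, n) {
  D <- ncol(gmm$means)
  comp <- sample.int(length(gmm$weights), n, replace = TRUE,
                     prob = gmm$weights)
  out <- matrix(0, n, D)
  for (k in unique(comp)) {
    idx <- comp == k
    ch <- chol(gmm$covs[[k]])
    out[idx, ] <- matrix(stats::rnorm(sum(idx) * D), ncol = D) %*% ch +
      matrix(gmm$means[k, ], sum(idx), D, byrow = TRUE)
  }
  out
}
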