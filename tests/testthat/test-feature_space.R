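test_that("mutual information matches limits and a brute-force table oracle", {
  set.seed(1)
  # constant feature carries nothing
  expect_equal(mutual_information(replicate(4, rep(2.5, 50),
                                            simplify = FALSE)), 0)
  # deterministic distinct value per cell on 4 uniform cells: log2(4)
  det <- lapply(c(0, 1, 2, 3), function(v) rep(v, 50))
  expect_equal(mutual_information(det, n_bins = 8), 2)
  # label-independent feature: near zero (plug-in bias is
  # ~ (bins-1)(cells-1)/(2 N ln 2) bits, so use enough samples per cell)
  indep <- replicate(5, rnorm(1500), simplify = FALSE)
  expect_lte(mutual_information(indep), 0.05)
  # brute-force oracle on a small discrete joint table
  vals <- c(0.1, 0.5, 0.9)
  samples <- list(rep(vals, c(30, 10, 10)), rep(vals, c(5, 40, 5)),
                  rep(vals, c(10, 10, 30)))
  got <- mutual_information(samples, n_bins = 3)
  # direct double sum over the exact joint distribution
  p_xg <- vapply(samples, function(x) table(factor(x, levels = vals)) /
                   length(x), numeric(3))
  p_g <- rep(1 / 3, 3)
  p_x <- as.numeric(p_xg %*% p_g)
  want <- sum(vapply(1:3, function(g) sum(ifelse(p_xg[, g] > 0,
    p_g[g] * p_xg[, g] * log2(p_xg[, g] / p_x), 0)), numeric(1)))
  expect_equal(got, want, tolerance = 1e-12)
  expect_warning(mutual_information(list(rnorm(10))), "single populated")
})

test_that("ranking is deterministic and purely rank-based", {
  set.seed(2)
  mi <- runif(68)
  r <- rank_and_select(mi, 25)
  expect_equal(sort(r$rank_order), 1:68)
  expect_equal(r$selected, sort(order(-mi)[1:25]))
  expect_equal(rank_and_select(mi, 68)$selected, 1:68)
  # scaling MI leaves the selection unchanged
  expect_equal(rank_and_select(mi * 17, 25)$selected, r$selected)
  # ties break toward the smaller index, stable across calls
  mi_t <- rep(c(0.5, 0.2), c(10, 58))
  r1 <- rank_and_select(mi_t, 12); r2 <- rank_and_select(mi_t, 12)
  expect_identical(r1$selected, r2$selected)
  expect_equal(r1$selected, c(1:10, 11:12))
})

test_that("PCA is orthonormal, ordered, and reconstructs", {
  set.seed(3)
  n <- 400; p <- 10
  X <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(seq(5, 0.5, length.out = p)))
  m <- fit_pca(X, n_components = p)
  W <- m$loadings_full
  expect_equal(crossprod(W), diag(p), tolerance = 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_equal(sum(m$eigen_fractions), 1)
  # full back-projection reconstructs the standardized data
  Xs <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
  expect_equal(Xs %*% W %*% t(W), Xs, tolerance = 1e-8)
  # rank-1 data: first component carries ~ all variance
  t_ <- rnorm(n)
  X1 <- outer(t_, runif(p)) + matrix(rnorm(n * p, sd = 1e-4), n, p)
  m1 <- fit_pca(X1, 3)
  expect_gt(m1$eigen_fractions[1], 0.999)
  # zero-variance columns are dropped with a warning
  expect_warning(fit_pca(cbind(X, 7), 3), "zero-variance")
})

test_that("projection maps the mean to the origin and matches eigenvalues", {
  set.seed(4)
  X <- matrix(rnorm(2000 * 5), 2000, 5) %*%
    matrix(rnorm(25), 5, 5)
  m <- fit_pca(X, 3)
  sc0 <- project(matrix(m$center, 1), m)
  expect_equal(as.numeric(sc0), c(0, 0, 0), tolerance = 1e-12)
  sc <- project(X, m)
  expect_equal(diag(stats::cov(sc)), m$eigenvalues[1:3], tolerance = 1e-8,
               ignore_attr = TRUE)
  # out-of-range rows are flagged but produce finite scores
  X_out <- matrix(m$center, 2, 5, byrow = TRUE)
  X_out[2, 1] <- max(X[, 1]) + 100
  sc2 <- project(X_out, m)
  expect_true(all(is.finite(sc2)))
  expect_equal(attr(sc2, "extrapolated"), c(FALSE, TRUE))
})

test_that("sensitivity maps equal brute-force finite differences", {
  grid <- parameter_grid(c(0, 0.4), c(0, 0.6), 0.1)
  gi <- grid$gi_values; gc <- grid$gc_values
  lin <- outer(gi, rep(1, length(gc)))          # f = g_i
  sm <- sensitivity_map(lin, grid)
  expect_equal(sm$sens_gi, 0.1 / max(gi))       # step / peak
  expect_equal(sm$sens_gc, 0)
  both <- outer(gi, gc, `+`)
  sm2 <- sensitivity_map(both, grid)
  expect_equal(sm2$sens_gi, sm2$sens_gc)
  set.seed(5)
  rnd <- matrix(runif(length(gi) * length(gc)), length(gi))
  sm3 <- sensitivity_map(rnd, grid)
  nrm <- rnd / max(abs(rnd))
  expect_equal(sm3$sens_gi, mean(nrm[-1, ] - nrm[-nrow(nrm), ]))
  expect_equal(sm3$sens_gc, mean(nrm[, -1] - nrm[, -ncol(nrm)]))
  expect_equal(sensitivity_map(matrix(0, length(gi), length(gc)),
                               grid)$sens_gi, 0)
})
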