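#' Index of a (g_i, g_c) cell inside a parameter grid
#' @keywords internal
cell_index <- function(grid, gi, gc) {
  i <- which(abs(grid$gi_values - gi) < 1e-9)
  j <- which(abs(grid$gc_values - gc) < 1e-9)
  if (!length(i) || !length(j))
    stop(sprintf("(g_i = %g, g_c = %g) is not on the parameter grid", gi, gc))
  (j - 1L) * length(grid$gi_values) + i
}

#' Fit the forward model: one Gaussian mixture per grid cell
#'
#' The forward model is the simulation-derived likelihood
#' \eqn{P(y | g_i, g_c)} over the 3-D PCA score space, represented as an
#' independent variational-Bayes Gaussian mixture per grid cell.
#' Per-cell seeds derive from the cell index, so results do not depend
#' on evaluation order.
#'
#' @param scores_by_cell list of score matrices, one per grid cell in
#'   grid order (`g_i` varying fastest), as produced by
#'   [library_scores()].
#' @param grid the [parameter_grid()].
#' @param max_K maximum mixture size per cell (default 20).
#' @param seed base seed.
#' @param transform optional feature-space transform (list with
#'   `ranking` and `pca`) stored for later projection of data.
#' @return object of class `forward_model`: `grid`, `gmms`,
#'   `mean_effective_K`, `transform`.
#' @export
build_forward_model <- function(scores_by_cell, grid, max_K = 20L,
                                seed = 1L, transform = NULL) {
  cells <- grid_cells(grid)
  if (length(scores_by_cell) != nrow(cells))
    stop("scores_by_cell must have one entry per grid cell")
  missing_cells <- which(vapply(scores_by_cell, function(s)
    is.null(s) || nrow(as.matrix(s)) == 0L, logical(1)))
  if (length(missing_cells))
    stop("no scores for grid cell(s): ",
         paste(sprintf("(%g, %g)", cells$gi[missing_cells],
                       cells$gc[missing_cells]), collapse = ", "))
  gmms <- lapply(seq_along(scores_by_cell), function(ci)
    fit_cell_gmm(scores_by_cell[[ci]], max_K = max_K,
                 seed = derive_seed(seed, ci)))
  structure(list(grid = grid, gmms = gmms,
                 mean_effective_K =
                   mean(vapply(gmms, `[[`, integer(1), "effective_K")),
                 transform = transform),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("<forward_model> %d cells, mean effective K = %.2f\n",
              length(x$gmms), x$mean_effective_K))
  invisible(x)
}

#' Log-likelihood of score points under one grid cell of the forward model
#'
#' @param y 3-D point (vector) or matrix of points (rows).
#' @param g numeric length-2 `(g_i, g_c)`; must lie on the grid.
#' @param fm a [build_forward_model()] object.
#' @return log-density value(s), finite for finite `y`.
#' @export
log_likelihood <- function(y, g, fm) {
  gmm_log_density(fm$gmms[[cell_index(fm$grid, g[1], g[2])]], y)
}

#' Two-sample energy test (Aslan-Zech) with permutation p-value
#'
#' Statistic with logarithmic distance kernel `R(r) = -ln(r + eps)`:
#' \deqn{\Phi = \frac{1}{n_a^2}\sum_{i<j} R(|a_i-a_j|) +
#'             \frac{1}{n_b^2}\sum_{i<j} R(|b_i-b_j|) -
#'             \frac{1}{n_a n_b}\sum_{i,j} R(|a_i-b_j|)}
#' Large values indicate distributional difference; the p-value is the
#' permutation tail probability over `n_perm` label shuffles (with the
#' +1 correction).
#'
#' @param a,b numeric matrices of points (rows), each with >= 10 rows.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @param eps kernel offset guarding `log(0)`.
#' @return list with `statistic` and `p_value`.
#' @export
energy_test <- function(a, b, n_perm = 1000L, seed = 1L, eps = 1e-12) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) >= 10L, nrow(b) >= 10L, ncol(a) == ncol(b))
  na <- nrow(a); nb <- nrow(b); n <- na + nb
  R <- -log(as.matrix(stats::dist(rbind(a, b))) + eps)
  diag(R) <- 0
  stat_for <- function(ia) {
    za <- rep(0, n); za[ia] <- 1
    Rza <- R %*% za
    saa <- drop(crossprod(za, Rza)) / 2
    stot <- sum(Rza)                      # sum over all pairs vs a
    sab <- stot - 2 * saa
    sbb <- (sum(R) / 2) - saa - sab
    saa / na^2 + sbb / nb^2 - sab / (na * nb)
  }
  obs <- stat_for(seq_len(na))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    stat_for(sample.int(n, na)), numeric(1))
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' Goodness-of-fit check of a forward model against its training scores
#'
#' For each grid cell, draws a model sample of the same size as the
#' cell's score set and runs the energy test.  Mirrors the published
#' protocol where the fit was accepted when the difference was not
#' significant (p > 0.1) for most cells.
#'
#' @param fm a [build_forward_model()] object.
#' @param scores_by_cell the per-cell training scores.
#' @param n_perm permutations per cell.
#' @param seed base seed.
#' @return data.frame with `gi`, `gc`, `statistic`, `p_value`.
#' @export
check_forward_model <- function(fm, scores_by_cell, n_perm = 200L,
                                seed = 1L) {
  cells <- grid_cells(fm$grid)
  res <- lapply(seq_along(fm$gmms), function(ci) {
    sc <- as.matrix(scores_by_cell[[ci]])
    set.seed(derive_seed(seed, ci))
    samp <- gmm_sample(fm$gmms[[ci]], nrow(sc))
    et <- energy_test(sc, samp, n_perm = n_perm,
                      seed = derive_seed(seed, ci + 7L))
    data.frame(gi = cells$gi[ci], gc = cells$gc[ci],
               statistic = et$statistic, p_value = et$p_value)
  })
  do.call(rbind, res)
}
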