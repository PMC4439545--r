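#' Plug-in mutual information between a feature and the grid label
#'
#' Histogram estimator of \eqn{I(G; x)} with the cell label \eqn{g}
#' uniform over populated cells and \eqn{P(x|g)} a per-cell histogram on
#' shared equal-width bins spanning the pooled range of the feature.
#' Base-2 logarithm, with the convention \eqn{0 \log 0 = 0}; tiny
#' negative round-off is clipped to 0.
#'
#' @param samples_by_cell list of numeric vectors, one per populated
#'   grid cell (NAs dropped).
#' @param n_bins number of shared histogram bins (default 50).
#' @return mutual information in bits (>= 0).
#' @export
mutual_information <- function(samples_by_cell, n_bins = 50L) {
  stopifnot(n_bins >= 2L)
  samples_by_cell <- lapply(samples_by_cell, function(x) x[!is.na(x)])
  samples_by_cell <- samples_by_cell[lengths(samples_by_cell) > 0L]
  n_g <- length(samples_by_cell)
  if (n_g < 1L) stop("no populated cells")
  if (n_g == 1L) {
    warning("single populated cell: mutual information is 0")
    return(0)
  }
  pooled <- unlist(samples_by_cell, use.names = FALSE)
  lo <- min(pooled); hi <- max(pooled)
  if (hi - lo <= 0) return(0)  # constant feature carries no information
  width <- (hi - lo) / n_bins
  bin_of <- function(x) pmin(floor((x - lo) / width) + 1L, n_bins)
  p_xg <- vapply(samples_by_cell, function(x) {
    tabulate(bin_of(x), nbins = n_bins) / length(x)
  }, numeric(n_bins))                       # n_bins x n_g
  p_g <- rep(1 / n_g, n_g)
  p_x <- as.numeric(p_xg %*% p_g)
  mi <- 0
  for (g in seq_len(n_g)) {
    nz <- p_xg[, g] > 0
    mi <- mi + p_g[g] *
      sum(p_xg[nz, g] * log2(p_xg[nz, g] / p_x[nz]))
  }
  max(mi, 0)
}

#' Rank features by mutual information and select the top k
#'
#' Descending MI with deterministic tie-breaking toward the smaller
#' feature index; selection is purely rank-based.
#'
#' @param mi numeric vector of per-feature MI values (one per feature,
#'   typically length 68).
#' @param k number of features to keep (default 25).
#' @return object of class `mi_ranking`: `mi`, `rank_order`
#'   (permutation, best first) and `selected` (sorted top-k indices).
#' @export
rank_and_select <- function(mi, k = 25L) {
  stopifnot(k >= 1L, k <= length(mi), all(mi >= 0 | is.na(mi)))
  ord <- order(-mi, seq_along(mi))
  structure(list(mi = mi, rank_order = ord,
                 selected = sort(ord[seq_len(k)]), k = as.integer(k)),
            class = "mi_ranking")
}

#' Fit the PCA embedding of the selected features
#'
#' Features are z-scored before the eigen-decomposition of their
#' covariance (the blocks have incommensurable units: Hz, counts,
#' fractions).  Components are ordered by decreasing eigenvalue; the
#' sign convention makes the largest-magnitude loading of each component
#' positive.  Zero-variance columns are dropped with a warning.
#'
#' @param X numeric matrix, rows = segments, columns = selected
#'   features; no sentinel (NA) rows.
#' @param n_components number of components to keep (default 3).
#' @param standardize z-score the columns first (default `TRUE`)?
#' @return object of class `pca_model`: `center`, `scale`, `loadings`
#'   (orthonormal, kept columns), `eigenvalues`, `eigen_fractions`,
#'   `n_components`, `kept_cols`, `train_range`.
#' @export
fit_pca <- function(X, n_components = 3L, standardize = TRUE) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("sentinel (NA) rows must be excluded before PCA")
  sds <- apply(X, 2L, stats::sd)
  kept <- which(sds > 0)
  if (length(kept) < ncol(X))
    warning(sprintf("dropping %d zero-variance feature(s) before PCA",
                    ncol(X) - length(kept)))
  X <- X[, kept, drop = FALSE]
  ctr <- colMeans(X)
  scl <- if (standardize) sds[kept] else rep(1, length(kept))
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  ev <- eigen(stats::cov(Xs), symmetric = TRUE)
  W <- ev$vectors
  lam <- pmax(ev$values, 0)
  for (j in seq_len(ncol(W)))       # sign convention
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  n_components <- min(n_components, ncol(W))
  structure(list(center = ctr, scale = scl,
                 loadings = W[, seq_len(n_components), drop = FALSE],
                 loadings_full = W,
                 eigenvalues = lam,
                 eigen_fractions = lam / sum(lam),
                 n_components = as.integer(n_components),
                 kept_cols = kept,
                 train_range = apply(X, 2L, range)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d features -> %d components; eigenvalue fractions %s\n",
              length(x$center), x$n_components,
              paste(sprintf("%.2f", x$eigen_fractions[seq_len(x$n_components)]),
                    collapse = ", ")))
  invisible(x)
}

#' Project feature rows into the fitted PCA space
#'
#' @param X matrix whose columns match the features the model was fit
#'   on (before zero-variance dropping).
#' @param model a [fit_pca()] model.
#' @return matrix of scores, rows = input rows, columns = kept
#'   components.  Rows containing values outside the training range are
#'   marked in the logical attribute `extrapolated`.
#' @export
project <- function(X, model) {
  X <- as.matrix(X)
  if (ncol(X) < max(model$kept_cols))
    stop("column count does not match the fitted feature set")
  X <- X[, model$kept_cols, drop = FALSE]
  extrap <- vapply(seq_len(nrow(X)), function(i)
    any(X[i, ] < model$train_range[1, ] | X[i, ] > model$train_range[2, ]),
    logical(1))
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  sc <- Xs %*% model$loadings
  attr(sc, "extrapolated") <- extrap
  sc
}

#' Sensitivity of a feature surface to each conductance axis
#'
#' The per-cell mean feature surface is normalized by its peak absolute
#' value; sensitivity along each axis is the mean forward difference of
#' the normalized surface across the whole grid.
#'
#' @param feature_surface matrix, rows indexed by `gi_values`, columns
#'   by `gc_values`.
#' @param grid the [parameter_grid()] the surface lives on.
#' @return object of class `sensitivity_map`: `surface` (peak-
#'   normalized), `sens_gi`, `sens_gc`.
#' @export
sensitivity_map <- function(feature_surface, grid) {
  S <- as.matrix(feature_surface)
  stopifnot(nrow(S) == length(grid$gi_values),
            ncol(S) == length(grid$gc_values))
  peak <- max(abs(S))
  Sn <- if (peak > 0) S / peak else S * 0
  sens_gi <- if (nrow(Sn) > 1) mean(diff(Sn)) else 0
  sens_gc <- if (ncol(Sn) > 1) mean(t(diff(t(Sn)))) else 0
  structure(list(surface = Sn, sens_gi = sens_gi, sens_gc = sens_gc),
            class = "sensitivity_map")
}
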