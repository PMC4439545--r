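#' Paired control / pharmacological segment scores for one neuron
#'
#' @param con_scores,pha_scores matrices of per-segment 3-D PCA scores
#'   (rows = segments), same number of rows.
#' @param pha `"PIX"` (blocks g_i; g_c shared with control) or `"CBX"`
#'   (blocks g_c; g_i shared with control).
#' @return object of class `condition_pair`.
#' @export
condition_pair <- function(con_scores, pha_scores, pha = c("PIX", "CBX")) {
  pha <- match.arg(pha)
  con_scores <- as.matrix(con_scores); pha_scores <- as.matrix(pha_scores)
  if (nrow(con_scores) != nrow(pha_scores))
    stop("both conditions must have the same number of segments")
  structure(list(con = con_scores, pha = pha_scores, pha_label = pha,
                 n_segments = nrow(con_scores)),
            class = "condition_pair")
}

#' Per-segment log-likelihood table over all grid cells
#'
#' @param pair a [condition_pair()].
#' @param fm a [build_forward_model()] object.
#' @return object of class `likelihood_table`: `loglik` is a list with
#'   elements `con` and `pha`, each a list of `n_gi x n_gc` log-density
#'   matrices (one per segment); plus `grid`, `pha_label`, `n_segments`.
#' @export
segment_likelihood_table <- function(pair, fm) {
  grid <- fm$grid
  n_gi <- length(grid$gi_values); n_gc <- length(grid$gc_values)
  cells <- grid_cells(grid)
  per_cond <- function(scores) {
    lapply(seq_len(nrow(scores)), function(t) {
      ll <- vapply(seq_len(nrow(cells)), function(ci)
        gmm_log_density(fm$gmms[[ci]], scores[t, ]), numeric(1))
      matrix(ll, n_gi, n_gc)   # g_i varies fastest in grid order
    })
  }
  structure(list(loglik = list(con = per_cond(pair$con),
                               pha = per_cond(pair$pha)),
                 grid = grid, pha_label = pair$pha_label,
                 n_segments = pair$n_segments),
            class = "likelihood_table")
}

#' Standard deviations of the segment-level prior for one condition
#'
#' Variance sharing under the commonality constraint: for a PIX pairing
#' the shared g_c axes use sigma2 (g_i uses sigma1 under CON, sigma3
#' under PIX); for a CBX pairing the shared g_i axes use sigma1 (g_c
#' uses sigma2 under CON, sigma3 under CBX).
#'
#' @param hp numeric length-3 `(sigma1, sigma2, sigma3)`.
#' @param pha `"PIX"` or `"CBX"`.
#' @param condition `"CON"` or the pharmacological condition.
#' @return numeric length-2 `(sd_gi, sd_gc)`.
#' @export
prior_sigmas <- function(hp, pha, condition) {
  stopifnot(length(hp) == 3L, all(hp >= 0))
  if (pha == "PIX") {
    if (condition == "CON") c(hp[1], hp[2]) else c(hp[3], hp[2])
  } else {
    if (condition == "CON") c(hp[1], hp[2]) else c(hp[1], hp[3])
  }
}

# n x n matrix: column j is the discrete Gaussian over `values` centered
# at values[j] with sd `sigma`, renormalized; sigma = 0 is a point mass.
axis_prior_matrix <- function(values, sigma) {
  if (sigma < 0) stop("prior standard deviation must be >= 0")
  n <- length(values)
  if (sigma == 0) return(diag(n))
  M <- outer(values, values, function(a, b)
    stats::dnorm(a, mean = b, sd = sigma))
  sweep(M, 2L, colSums(M), "/")
}

#' Discrete hierarchical prior over segment-level cells
#'
#' Product of axis-wise discrete Gaussians centered on the neuron-level
#' cell; each axis renormalized to sum 1 on the grid.  `sigma = 0`
#' degenerates to a point mass.
#'
#' @param neuron_g numeric length-2 `(g_i, g_c)` on the grid.
#' @param hp `(sigma1, sigma2, sigma3)`.
#' @param pha `"PIX"` or `"CBX"`.
#' @param grid the [parameter_grid()].
#' @param condition `"CON"` or the pharmacological condition.
#' @return `n_gi x n_gc` matrix of probabilities summing to 1.
#' @export
hierarchical_prior <- function(neuron_g, hp, pha, grid,
                               condition = "CON") {
  sig <- prior_sigmas(hp, pha, condition)
  i <- which(abs(grid$gi_values - neuron_g[1]) < 1e-9)
  j <- which(abs(grid$gc_values - neuron_g[2]) < 1e-9)
  if (!length(i) || !length(j))
    stop("neuron-level cell is not on the grid")
  p_gi <- axis_prior_matrix(grid$gi_values, sig[1])[, i]
  p_gc <- axis_prior_matrix(grid$gc_values, sig[2])[, j]
  outer(p_gi, p_gc)
}

# integrated log-likelihood surface over neuron-level (Gi, Gc) for one
# condition: log prod_t sum_cells exp(L_t) * prior(. | Gi, Gc)
condition_integrated_loglik <- function(L_list, sd_gi, sd_gc, grid) {
  Ai <- axis_prior_matrix(grid$gi_values, sd_gi)
  Ac <- axis_prior_matrix(grid$gc_values, sd_gc)
  total <- matrix(0, length(grid$gi_values), length(grid$gc_values))
  for (L in L_list) {
    mx <- max(L)
    M <- crossprod(Ai, exp(L - mx)) %*% Ac
    total <- total + log(pmax(M, .Machine$double.xmin)) + mx
  }
  total
}

#' Integrated log-likelihood of all segments given one neuron-level cell
#'
#' Grid-sum replacement of the hierarchical integral: per segment and
#' condition, the segment likelihood is summed over segment-level cells
#' weighted by the hierarchical prior; log-products accumulate across
#' segments.
#'
#' @param table a [segment_likelihood_table()].
#' @param neuron_g list with elements `con` and `pha`, each
#'   `(g_i, g_c)` on the grid (the commonality equality must hold).
#' @param hp `(sigma1, sigma2, sigma3)`.
#' @return scalar log-likelihood.
#' @export
integrate_segment_likelihood <- function(table, neuron_g, hp) {
  grid <- table$grid; pha <- table$pha_label
  total <- 0
  for (cond in c("con", "pha")) {
    cname <- if (cond == "con") "CON" else pha
    pr <- hierarchical_prior(neuron_g[[cond]], hp, pha, grid, cname)
    lpr <- log(pr)
    for (L in table$loglik[[cond]])
      total <- total + logsumexp(as.numeric(L + lpr))
  }
  total
}

# lattice axis layout under the delta commonality prior
constrained_axes <- function(grid, pha) {
  if (pha == "PIX")
    list(a = grid$gi_values, b = grid$gi_values, shared = grid$gc_values,
         a_name = "gi_CON", b_name = "gi_PIX", shared_name = "gc")
  else
    list(a = grid$gc_values, b = grid$gc_values, shared = grid$gi_values,
         a_name = "gc_CON", b_name = "gc_CBX", shared_name = "gi")
}

#' Posterior over the constrained conductance lattice, with evidence
#'
#' The delta commonality prior collapses one of the four conductance
#' axes exactly: for PIX the lattice is (g_i^CON, g_i^PIX, shared g_c),
#' for CBX (g_c^CON, g_c^CBX, shared g_i).  The prior over the lattice
#' is uniform; the evidence is the log mean integrated likelihood.
#'
#' @param table a [segment_likelihood_table()].
#' @param hp `(sigma1, sigma2, sigma3)`; all zeros gives the
#'   non-segmental model.
#' @return object of class `posterior_map`: `probs` (3-d array summing
#'   to 1, dims a x b x shared), `log_evidence`, `map` (list `con`,
#'   `pha` of on-grid `(g_i, g_c)`), `hp`, `pha_label`, `axes`.
#' @export
posterior_and_evidence <- function(table, hp = c(0, 0, 0)) {
  grid <- table$grid; pha <- table$pha_label
  S_con <- condition_integrated_loglik(
    table$loglik$con, prior_sigmas(hp, pha, "CON")[1],
    prior_sigmas(hp, pha, "CON")[2], grid)
  S_pha <- condition_integrated_loglik(
    table$loglik$pha, prior_sigmas(hp, pha, pha)[1],
    prior_sigmas(hp, pha, pha)[2], grid)
  ax <- constrained_axes(grid, pha)
  na <- length(ax$a); nb <- length(ax$b); ns <- length(ax$shared)
  lp <- array(-Inf, dim = c(na, nb, ns))
  if (pha == "PIX") {
    # S[gi, gc]: lattice (gi_CON = a, gi_PIX = b, gc = shared)
    for (c_ in seq_len(ns))
      lp[, , c_] <- outer(S_con[, c_], S_pha[, c_], `+`)
  } else {
    # S[gi, gc]: lattice (gc_CON = a, gc_CBX = b, gi = shared)
    for (c_ in seq_len(ns))
      lp[, , c_] <- outer(S_con[c_, ], S_pha[c_, ], `+`)
  }
  if (all(!is.finite(lp)))
    stop("model cannot explain the data: all-(-Inf) likelihood")
  lse <- logsumexp(as.numeric(lp))
  probs <- exp(lp - lse)
  log_evidence <- lse - log(na * nb * ns)   # uniform lattice prior
  # MAP with deterministic lexicographic tie-break (a, then b, then shared)
  best <- which(probs == max(probs), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2], best[, 3])[1], , drop = TRUE]
  map <- if (pha == "PIX")
    list(con = c(gi = ax$a[best[1]], gc = ax$shared[best[3]]),
         pha = c(gi = ax$b[best[2]], gc = ax$shared[best[3]]))
  else
    list(con = c(gi = ax$shared[best[3]], gc = ax$a[best[1]]),
         pha = c(gi = ax$shared[best[3]], gc = ax$b[best[2]]))
  structure(list(probs = probs, log_evidence = log_evidence, map = map,
                 hp = hp, pha_label = pha, axes = ax),
            class = "posterior_map")
}

#' @export
print.posterior_map <- function(x, ...) {
  cat(sprintf("<posterior_map> %s pairing, log evidence %.3f\n",
              x$pha_label, x$log_evidence))
  cat(sprintf("  MAP CON (gi, gc) = (%g, %g); %s (gi, gc) = (%g, %g)\n",
              x$map$con[1], x$map$con[2], x$pha_label,
              x$map$pha[1], x$map$pha[2]))
  invisible(x)
}

#' Exhaustive evidence search over the sigma lattice
#'
#' All `(sigma1, sigma2, sigma3)` combinations on the given lattice are
#' scored by model evidence; ties break toward smaller sigmas
#' lexicographically.  The search exploits that the two conditions
#' depend on disjoint sigma pairs, so integrated likelihood surfaces are
#' cached per axis value.
#'
#' @param table a [segment_likelihood_table()].
#' @param sigma_values candidate values per axis (default
#'   `seq(0, 0.5, by = 0.025)`).
#' @return list with `hp`, `posterior` (the [posterior_and_evidence()]
#'   result at the optimum) and `evidence_table` (data.frame of all
#'   combinations).
#' @export
optimize_hyperparams <- function(table,
                                 sigma_values = seq(0, 0.5, by = 0.025)) {
  stopifnot(length(sigma_values) >= 1L, all(sigma_values >= 0))
  grid <- table$grid; pha <- table$pha_label
  sv <- sort(unique(sigma_values))
  # evidence from the two integrated surfaces without forming the lattice
  ev_from <- function(S_con, S_pha) {
    if (pha == "PIX") {
      # sum over (a, b, c) of exp(S_con[a,c] + S_pha[b,c])
      la <- apply(S_con, 2L, logsumexp)
      lb <- apply(S_pha, 2L, logsumexp)
      logsumexp(la + lb) -
        log(length(grid$gi_values)^2 * length(grid$gc_values))
    } else {
      la <- apply(S_con, 1L, logsumexp)
      lb <- apply(S_pha, 1L, logsumexp)
      logsumexp(la + lb) -
        log(length(grid$gc_values)^2 * length(grid$gi_values))
    }
  }
  rows <- list(); best <- NULL
  if (pha == "PIX") {
    # CON depends on (s1, s2); PIX on (s3, s2)
    for (s2 in sv) {
      Sc <- lapply(sv, function(s1) condition_integrated_loglik(
        table$loglik$con, s1, s2, grid))
      Sp <- lapply(sv, function(s3) condition_integrated_loglik(
        table$loglik$pha, s3, s2, grid))
      for (i1 in seq_along(sv)) for (i3 in seq_along(sv)) {
        ev <- ev_from(Sc[[i1]], Sp[[i3]])
        rows[[length(rows) + 1L]] <-
          c(sigma1 = sv[i1], sigma2 = s2, sigma3 = sv[i3], evidence = ev)
      }
    }
  } else {
    # CON depends on (s1, s2); CBX on (s1, s3)
    for (s1 in sv) {
      Sc <- lapply(sv, function(s2) condition_integrated_loglik(
        table$loglik$con, s1, s2, grid))
      Sp <- lapply(sv, function(s3) condition_integrated_loglik(
        table$loglik$pha, s1, s3, grid))
      for (i2 in seq_along(sv)) for (i3 in seq_along(sv)) {
        ev <- ev_from(Sc[[i2]], Sp[[i3]])
        rows[[length(rows) + 1L]] <-
          c(sigma1 = s1, sigma2 = sv[i2], sigma3 = sv[i3], evidence = ev)
      }
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  ord <- order(-tab$evidence, tab$sigma1, tab$sigma2, tab$sigma3)
  hp <- as.numeric(tab[ord[1L], c("sigma1", "sigma2", "sigma3")])
  list(hp = hp, posterior = posterior_and_evidence(table, hp),
       evidence_table = tab)
}

new_estimate <- function(method, post, hp = NULL, table = NULL) {
  structure(list(method = method,
                 map_con = post$map$con, map_pha = post$map$pha,
                 hp = hp, log_evidence = post$log_evidence,
                 posterior = post, table = table),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("<estimate_result> method = %s\n", x$method))
  cat(sprintf("  CON: gi = %g, gc = %g\n", x$map_con[1], x$map_con[2]))
  cat(sprintf("  pha: gi = %g, gc = %g\n", x$map_pha[1], x$map_pha[2]))
  if (!is.null(x$hp))
    cat(sprintf("  sigma = (%g, %g, %g)\n", x$hp[1], x$hp[2], x$hp[3]))
  invisible(x)
}

#' Segmental (hierarchical) Bayesian estimate of (g_i, g_c)
#'
#' Builds the per-segment likelihood table, optimizes the segment-level
#' prior variances by evidence, and returns the neuron-level MAP under
#' the commonality constraint.
#'
#' @param pair a [condition_pair()].
#' @param fm a [build_forward_model()] object.
#' @param sigma_values sigma search lattice (default
#'   `seq(0, 0.5, by = 0.025)`).
#' @param table optional precomputed [segment_likelihood_table()].
#' @return an `estimate_result` with `method = "segmental"`.
#' @export
estimate_segmental <- function(pair, fm,
                               sigma_values = seq(0, 0.5, by = 0.025),
                               table = NULL) {
  if (is.null(table)) table <- segment_likelihood_table(pair, fm)
  opt <- optimize_hyperparams(table, sigma_values)
  new_estimate("segmental", opt$posterior, hp = opt$hp, table = table)
}

#' Non-segmental Bayesian estimate (all sigmas fixed at zero)
#'
#' Equivalent to the segmental model with a point-mass segment prior:
#' the likelihood is the plain product over segments at the neuron-level
#' cell.
#'
#' @inheritParams estimate_segmental
#' @return an `estimate_result` with `method = "non_segmental"`.
#' @export
estimate_non_segmental <- function(pair, fm, table = NULL) {
  if (is.null(table)) table <- segment_likelihood_table(pair, fm)
  post <- posterior_and_evidence(table, c(0, 0, 0))
  new_estimate("non_segmental", post, hp = c(0, 0, 0), table = table)
}

# smallest (gi, gc) among candidate cell indices (gi breaks ties first)
pick_cell <- function(cells, idx) {
  sub <- cells[idx, , drop = FALSE]
  sub <- sub[order(sub$gi, sub$gc), , drop = FALSE]
  idx[order(cells$gi[idx], cells$gc[idx])[1L]]
}

#' Minimum-PCA-error baseline estimate
#'
#' Per segment, picks the grid cell whose nearest simulated score
#' (Euclidean, 3-D) is closest — the vanishing-variance limit of a
#' mixture likelihood with one Gaussian per simulated sample.  The
#' neuron-level estimate per condition is the mode over segments.  All
#' ties break toward smaller g_i, then smaller g_c.
#'
#' @param pair a [condition_pair()].
#' @param sim_scores_by_cell list of per-cell simulated score matrices
#'   in grid order.
#' @param grid the [parameter_grid()].
#' @return an `estimate_result` with `method = "min_error"` and a
#'   `per_segment` data.frame of segment-wise choices.
#' @export
estimate_min_error <- function(pair, sim_scores_by_cell, grid) {
  cells <- grid_cells(grid)
  nearest_d <- function(y, sc)
    sqrt(min(colSums((t(sc) - y)^2)))
  seg_cell <- function(y) {
    d <- vapply(sim_scores_by_cell, nearest_d, numeric(1), y = y)
    pick_cell(cells, which(d <= min(d) + 1e-12))
  }
  per_cond <- function(scores) {
    vapply(seq_len(nrow(scores)), function(t) seg_cell(scores[t, ]),
           integer(1))
  }
  mode_cell <- function(idx) {
    tb <- table(idx)
    winners <- as.integer(names(tb)[tb == max(tb)])
    pick_cell(cells, winners)
  }
  con_idx <- per_cond(pair$con); pha_idx <- per_cond(pair$pha)
  ci <- mode_cell(con_idx); pi_ <- mode_cell(pha_idx)
  post <- list(map = list(con = c(gi = cells$gi[ci], gc = cells$gc[ci]),
                          pha = c(gi = cells$gi[pi_], gc = cells$gc[pi_])),
               log_evidence = NA_real_)
  res <- new_estimate("min_error", post)
  res$per_segment <- data.frame(
    condition = rep(c("CON", pair$pha_label), each = pair$n_segments),
    segment = rep(seq_len(pair$n_segments), 2L),
    gi = cells$gi[c(con_idx, pha_idx)], gc = cells$gc[c(con_idx, pha_idx)])
  res
}

#' Mean PCA-space error of an estimate
#'
#' Mean Euclidean distance between each data segment's score and the
#' closest simulated score of the estimated cell, averaged over both
#' conditions.
#'
#' @param est an `estimate_result`.
#' @param pair the [condition_pair()] that was estimated.
#' @param sim_scores_by_cell per-cell simulated score matrices.
#' @param grid the [parameter_grid()].
#' @return non-negative scalar.
#' @export
pca_error_rate <- function(est, pair, sim_scores_by_cell, grid) {
  err_cond <- function(scores, g) {
    sc <- sim_scores_by_cell[[cell_index(grid, g[1], g[2])]]
    mean(vapply(seq_len(nrow(scores)), function(t)
      sqrt(min(colSums((t(sc) - scores[t, ])^2))), numeric(1)))
  }
  mean(c(err_cond(pair$con, est$map_con),
         err_cond(pair$pha, est$map_pha)))
}
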