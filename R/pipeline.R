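#' Default neuron triplets of a recording
#'
#' Features are averaged within triplets of neurons.  For the 3 x 3
#' simulated lattice the three rows (nearest-neighbour triplets) are
#' used; a 3-neuron recording is a single triplet.
#' @param n_neurons number of neurons in the recording.
#' @return list of integer index triplets.
#' @export
default_triplets <- function(n_neurons) {
  if (n_neurons == 3L) return(list(1:3))
  side <- as.integer(round(sqrt(n_neurons)))
  if (side * side == n_neurons && side >= 3L)
    return(lapply(seq_len(side), function(r) ((r - 1L) * side) + 1:3))
  stop("no default triplets for ", n_neurons, " neurons")
}

#' Feature matrix of one recording
#'
#' One row per (triplet, segment): the 68-component feature vector.
#'
#' @param s a [spike_train_set()].
#' @param seg_len segment length in seconds (default 50).
#' @param triplets list of neuron index triplets (default
#'   [default_triplets()]).
#' @return matrix with 68 named columns and attribute `flagged`
#'   (logical per row: contains undefined features).
#' @export
recording_features <- function(s, seg_len = 50, triplets = NULL) {
  if (is.null(triplets)) triplets <- default_triplets(length(s$trains))
  segs <- segment_recording(s, seg_len)
  rows <- list(); flagged <- logical(0)
  for (tri in triplets) {
    trains <- s$trains[tri]
    for (t in seq_len(nrow(segs))) {
      fv <- compute_feature_vector(trains, segs[t, ])
      rows[[length(rows) + 1L]] <- fv
      flagged <- c(flagged, isTRUE(attr(fv, "flagged")))
    }
  }
  X <- do.call(rbind, rows)
  attr(X, "flagged") <- flagged
  X
}

#' Feature matrices for every cell of a simulation library
#'
#' @param lib a [run_grid_simulation()] library.
#' @param seg_len segment length in seconds.
#' @return list (grid order) of per-cell feature matrices; rows flagged
#'   as containing undefined features are dropped (their count is kept
#'   in the attribute `n_flagged`).
#' @export
library_features <- function(lib, seg_len = 50) {
  n_flagged <- 0L
  out <- lapply(lib$cells, function(cell) {
    X <- do.call(rbind, lapply(cell$sets, recording_features,
                               seg_len = seg_len))
    bad <- apply(X, 1L, anyNA)
    n_flagged <<- n_flagged + sum(bad)
    X[!bad, , drop = FALSE]
  })
  attr(out, "n_flagged") <- n_flagged
  out
}

#' Fit the shared feature-space transform (MI selection + PCA)
#'
#' @param features_by_cell list of per-cell feature matrices.
#' @param k number of features to keep by mutual information.
#' @param n_components PCA components to keep.
#' @param n_bins histogram bins of the MI estimator.
#' @return list with `ranking` (an `mi_ranking`) and `pca`
#'   (a `pca_model`).
#' @export
fit_feature_space <- function(features_by_cell, k = 25L,
                              n_components = 3L, n_bins = 50L) {
  p <- ncol(features_by_cell[[1L]])
  mi <- vapply(seq_len(p), function(f)
    mutual_information(lapply(features_by_cell, function(X) X[, f]),
                       n_bins = n_bins), numeric(1))
  ranking <- rank_and_select(mi, k)
  pooled <- do.call(rbind, features_by_cell)[, ranking$selected,
                                             drop = FALSE]
  pca <- fit_pca(pooled, n_components = n_components)
  list(ranking = ranking, pca = pca)
}

#' Project feature matrices through a fitted transform
#'
#' @param X feature matrix with the full 68 columns.
#' @param transform a [fit_feature_space()] transform.
#' @return score matrix (rows x kept components).
#' @export
transform_features <- function(X, transform) {
  project(X[, transform$ranking$selected, drop = FALSE], transform$pca)
}

#' Per-cell score matrices of a featurized library
#'
#' @param features_by_cell list of per-cell feature matrices.
#' @param transform a [fit_feature_space()] transform.
#' @return list of per-cell score matrices (grid order).
#' @export
library_scores <- function(features_by_cell, transform) {
  lapply(features_by_cell, transform_features, transform = transform)
}

#' Segment scores of one recording for one triplet
#'
#' Convenience wrapper: [recording_features()] followed by
#' [transform_features()].
#' @inheritParams recording_features
#' @param transform a [fit_feature_space()] transform.
#' @return score matrix, one row per (triplet, segment).
#' @export
recording_scores <- function(s, transform, seg_len = 50,
                             triplets = list(1:3)) {
  transform_features(recording_features(s, seg_len, triplets), transform)
}

#' Specification of a synthetic paired-condition fixture
#'
#' @param generator `"renewal"` (fast gamma-renewal surrogate) or
#'   `"surrogate_sim"` (the network simulator).
#' @param g_con,g_pha true `(g_i, g_c)` per condition; must obey the
#'   commonality structure of `pha`.
#' @param pha `"PIX"` or `"CBX"`.
#' @param sigma_true per-segment jitter SD of the generating parameters
#'   (0 = stationary truth).
#' @param n_neurons neurons per recording.
#' @param duration recording length in seconds.
#' @param seg_len segment length in seconds.
#' @param seed integer seed.
#' @param grid [parameter_grid()] the estimates will live on (recorded
#'   with the truth; jittered parameters are continuous and may fall
#'   between or outside its cells).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(generator = c("renewal", "surrogate_sim"),
                         g_con, g_pha, pha = c("PIX", "CBX"),
                         sigma_true = 0, n_neurons = 3L, duration = 500,
                         seg_len = 50, seed = 1L, grid = parameter_grid()) {
  generator <- match.arg(generator); pha <- match.arg(pha)
  if (pha == "PIX" && abs(g_con[2] - g_pha[2]) > 1e-9)
    stop("PIX pairing requires g_c^CON == g_c^PIX")
  if (pha == "CBX" && abs(g_con[1] - g_pha[1]) > 1e-9)
    stop("CBX pairing requires g_i^CON == g_i^CBX")
  structure(list(generator = generator, g_con = g_con, g_pha = g_pha,
                 pha = pha, sigma_true = sigma_true,
                 n_neurons = as.integer(n_neurons), duration = duration,
                 seg_len = seg_len, seed = as.integer(seed), grid = grid),
            class = "fixture_spec")
}

# gamma-renewal surrogate: firing rate falls with g_i, pairwise
# synchrony (shared mother spikes with small jitter) rises with g_c
renewal_trainset <- function(g_i, g_c, n_neurons, duration, condition) {
  rate <- 2.0 / (1 + g_i)             # Hz per neuron
  p_share <- min(g_c / (g_c + 0.6), 0.95)
  jit_sd <- 0.012                      # s, mother-spike copy jitter
  shape <- 2                           # gamma renewal shape
  mother_rate <- rate * p_share
  mother <- cumsum(stats::rexp(max(10, 3 * mother_rate * duration),
                               rate = max(mother_rate, 1e-9)))
  mother <- mother[mother < duration]
  trains <- lapply(seq_len(n_neurons), function(n) {
    own_rate <- rate * (1 - p_share)
    n_isi <- max(10, ceiling(3 * own_rate * duration))
    isis <- stats::rgamma(n_isi, shape = shape,
                          rate = shape * max(own_rate, 1e-9))
    own <- cumsum(isis); own <- own[own < duration]
    shared <- mother + stats::rnorm(length(mother), 0, jit_sd)
    ts <- sort(c(own, shared[shared >= 0 & shared < duration]))
    ts <- unique(round(ts, 4L))
    spike_train(ts, duration, sprintf("n%02d", n))
  })
  spike_train_set(trains, condition)
}

# one condition's recording, optionally with per-segment parameter jitter
fixture_condition <- function(spec, g_true, condition, seed) {
  n_seg <- floor(spec$duration / spec$seg_len)
  make_piece <- function(g, piece_seed, dur) {
    if (spec$generator == "surrogate_sim") {
      simulate_network(g[1], g[2],
                       sim_config(n_neurons = max(spec$n_neurons, 9L),
                                  duration = dur, noise_seed = piece_seed))
    } else {
      set.seed(piece_seed)
      renewal_trainset(g[1], g[2], spec$n_neurons, dur, "SIM")
    }
  }
  if (spec$sigma_true == 0) {
    s <- make_piece(g_true, seed, spec$duration)
    seg_params <- matrix(rep(g_true, n_seg), ncol = 2L, byrow = TRUE)
  } else {
    # continuous jitter, clamped at 0 only: segments may fall off the
    # estimation grid, emulating the model mismatch / non-stationarity
    # the hierarchical prior is meant to absorb
    set.seed(seed)
    gi_t <- pmax(stats::rnorm(n_seg, g_true[1], spec$sigma_true), 0)
    gc_t <- pmax(stats::rnorm(n_seg, g_true[2], spec$sigma_true), 0)
    seg_params <- cbind(gi_t, gc_t)
    pieces <- lapply(seq_len(n_seg), function(t)
      make_piece(c(gi_t[t], gc_t[t]), derive_seed(seed, t), spec$seg_len))
    n_tr <- length(pieces[[1L]]$trains)
    trains <- lapply(seq_len(n_tr), function(n) {
      ts <- unlist(lapply(seq_len(n_seg), function(t)
        pieces[[t]]$trains[[n]]$times + (t - 1) * spec$seg_len))
      spike_train(unique(round(ts, 4L)), spec$duration,
                  pieces[[1L]]$trains[[n]]$neuron_id)
    })
    s <- spike_train_set(trains, "SIM")
  }
  s$condition <- condition
  list(recording = s, seg_params = seg_params)
}

#' Generate a paired CON / pharmacological fixture with recorded truth
#'
#' The generating parameters obey the commonality structure of the
#' pairing; optional per-segment jitter of scale `sigma_true` emulates
#' non-stationary drift around the neuron-level truth.
#'
#' @param spec a [fixture_spec()].
#' @return list with `con`, `pha` ([spike_train_set()]s), `truth`
#'   (list `g_con`, `g_pha`, `sigma_true`, per-segment parameters).
#' @export
generate_fixture <- function(spec) {
  con <- fixture_condition(spec, spec$g_con, "CON", derive_seed(spec$seed, 1L))
  ph <- fixture_condition(spec, spec$g_pha, spec$pha,
                          derive_seed(spec$seed, 2L))
  list(con = con$recording, pha = ph$recording,
       truth = list(g_con = spec$g_con, g_pha = spec$g_pha,
                    pha = spec$pha, sigma_true = spec$sigma_true,
                    seg_params_con = con$seg_params,
                    seg_params_pha = ph$seg_params))
}

#' Build a full pipeline configuration
#'
#' @param gi_range,gc_range,step grid specification.
#' @param duration,n_neurons,n_realizations simulation library settings.
#' @param seg_len segment length (s).
#' @param k selected feature count; `n_components` PCA components.
#' @param max_K forward-model mixture cap.
#' @param sigma_values sigma search lattice.
#' @param seed master seed (every stage derives its own).
#' @param generator fixture generator for the demo estimation stage.
#' @return a named list of class `pipeline_config` (JSON round-trips
#'   losslessly via [write_pipeline_config()]).
#' @export
pipeline_config <- function(gi_range = c(0.4, 0.6), gc_range = c(0.9, 1.1),
                            step = 0.05, duration = 200, n_neurons = 9L,
                            n_realizations = 3L, seg_len = 50, k = 25L,
                            n_components = 3L, max_K = 20L,
                            sigma_values = seq(0, 0.5, by = 0.025),
                            seed = 1L, generator = "surrogate_sim") {
  if (is.null(seed)) stop("pipeline configuration requires a seed")
  structure(list(gi_range = gi_range, gc_range = gc_range, step = step,
                 duration = duration, n_neurons = as.integer(n_neurons),
                 n_realizations = as.integer(n_realizations),
                 seg_len = seg_len, k = as.integer(k),
                 n_components = as.integer(n_components),
                 max_K = as.integer(max_K), sigma_values = sigma_values,
                 seed = as.integer(seed), generator = generator),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$seed)) stop("pipeline configuration requires a seed")
  do.call(pipeline_config, raw)
}

#' Run the full estimation pipeline on synthetic data
#'
#' Executes the six stages end to end: grid simulation, feature
#' extraction, feature-space fit, forward-model fit, fixture generation
#' at the grid centre, and the three estimators.  Deterministic under
#' the configuration seed.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory for the manifest and result table.
#' @return list with `library`, `transform`, `forward_model`,
#'   `fixture`, `estimates` (list of the three `estimate_result`s),
#'   `errors` (named PCA error rates), `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  grid <- parameter_grid(cfg$gi_range, cfg$gc_range, cfg$step)
  lib <- run_grid_simulation(
    grid, sim_config(n_neurons = cfg$n_neurons, duration = cfg$duration,
                     noise_seed = derive_seed(cfg$seed, 11L)),
    n_realizations = cfg$n_realizations)
  feats <- library_features(lib, cfg$seg_len)
  transform <- fit_feature_space(feats, k = cfg$k,
                                 n_components = cfg$n_components)
  scores <- library_scores(feats, transform)
  fm <- build_forward_model(scores, grid, max_K = cfg$max_K,
                            seed = derive_seed(cfg$seed, 13L),
                            transform = transform)
  centre <- c(stats::median(grid$gi_values), stats::median(grid$gc_values))
  fx <- generate_fixture(fixture_spec(
    generator = cfg$generator, g_con = centre, g_pha = centre,
    pha = "PIX", sigma_true = 0,
    n_neurons = if (cfg$generator == "surrogate_sim") 9L else 3L,
    duration = cfg$duration, seg_len = cfg$seg_len,
    seed = derive_seed(cfg$seed, 17L), grid = grid))
  pair <- condition_pair(
    recording_scores(fx$con, transform, cfg$seg_len, list(1:3)),
    recording_scores(fx$pha, transform, cfg$seg_len, list(1:3)),
    "PIX")
  table <- segment_likelihood_table(pair, fm)
  est <- list(
    segmental = estimate_segmental(pair, fm, cfg$sigma_values,
                                   table = table),
    non_segmental = estimate_non_segmental(pair, fm, table = table),
    min_error = estimate_min_error(pair, scores, grid))
  errors <- vapply(est, pca_error_rate, numeric(1), pair = pair,
                   sim_scores_by_cell = scores, grid = grid)
  out <- list(library = lib, transform = transform, forward_model = fm,
              fixture = fx, pair = pair, estimates = est,
              errors = errors, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_config(cfg, file.path(out_dir, "manifest.json"))
    res <- do.call(rbind, lapply(names(est), function(m) data.frame(
      method = m,
      gi_con = est[[m]]$map_con[1], gc_con = est[[m]]$map_con[2],
      gi_pha = est[[m]]$map_pha[1], gc_pha = est[[m]]$map_pha[2],
      pca_error = errors[[m]])))
    utils::write.csv(res, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE)
  }
  out
}
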