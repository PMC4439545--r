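#' Discrete conductance grid
#'
#' The inverse problem is solved on a lattice of candidate
#' \eqn{(g_i, g_c)} values.  Defaults follow the reference protocol:
#' \eqn{g_i \in [0, 1.5]}, \eqn{g_c \in [0, 2.0]} mS/cm2 with a 0.05
#' increment, i.e. 31 x 41 = 1271 cells.
#'
#' @param gi_range,gc_range numeric length-2 inclusive ranges (mS/cm2).
#' @param step grid increment (mS/cm2).
#' @return object of class `parameter_grid` with fields `gi_values`,
#'   `gc_values`, `step`.
#' @export
parameter_grid <- function(gi_range = c(0, 1.5), gc_range = c(0, 2.0),
                           step = 0.05) {
  stopifnot(step > 0, length(gi_range) == 2L, length(gc_range) == 2L,
            gi_range[1] <= gi_range[2], gc_range[1] <= gc_range[2])
  n_of <- function(rng) {
    k <- (rng[2] - rng[1]) / step
    if (abs(k - round(k)) > 1e-9)
      stop("range is not an integer multiple of step")
    as.integer(round(k)) + 1L
  }
  gi <- gi_range[1] + step * (seq_len(n_of(gi_range)) - 1L)
  gc <- gc_range[1] + step * (seq_len(n_of(gc_range)) - 1L)
  structure(list(gi_values = gi, gc_values = gc, step = step),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("<parameter_grid> %d x %d = %d cells (step %.3g)\n",
              length(x$gi_values), length(x$gc_values),
              length(x$gi_values) * length(x$gc_values), x$step))
  invisible(x)
}

n_cells <- function(grid) length(grid$gi_values) * length(grid$gc_values)

#' All (g_i, g_c) cells of a grid as a data.frame (g_i varies fastest)
#' @keywords internal
grid_cells <- function(grid) {
  expand.grid(gi = grid$gi_values, gc = grid$gc_values,
              KEEP.OUT.ATTRS = FALSE)
}

#' Surrogate simulator configuration
#'
#' @param n_neurons lattice size; must be a perfect square (default 9,
#'   i.e. a 3 x 3 lattice).
#' @param duration simulated time in seconds.
#' @param g_e excitatory input conductance, fixed at 0.03 mS/cm2.
#' @param heterogeneity_frac maximum relative deviation of the
#'   heterogeneous conductances (uniform, default 5%).
#' @param noise_seed integer seed fixing every random draw of one run.
#' @param dt Euler-Maruyama step in seconds (default 1 ms).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 9L, duration = 200, g_e = 0.03,
                       heterogeneity_frac = 0.05, noise_seed = 1L,
                       dt = 1e-3) {
  stopifnot(duration >= 1, dt > 0,
            heterogeneity_frac >= 0, heterogeneity_frac < 1)
  side <- sqrt(n_neurons)
  if (abs(side - round(side)) > 1e-9)
    stop("n_neurons must be a perfect square lattice")
  structure(list(n_neurons = as.integer(n_neurons), duration = duration,
                 g_e = g_e, heterogeneity_frac = heterogeneity_frac,
                 noise_seed = as.integer(noise_seed), dt = dt),
            class = "sim_config")
}

#' Uniform conductance heterogeneity
#'
#' Draws `n` values uniformly on `[mean (1 - frac), mean (1 + frac)]`,
#' emulating cell-to-cell variability of membrane conductances.
#'
#' @param mean mean conductance.
#' @param frac maximum relative deviation (e.g. 0.05 for 5%).
#' @param n number of values.
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return numeric vector of length `n`.
#' @export
sample_heterogeneity <- function(mean, frac, n, seed = NULL) {
  stopifnot(mean >= 0, frac >= 0, frac < 1)
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n, mean * (1 - frac), mean * (1 + frac))
}

# 4-neighbour edges of a side x side lattice (0-based, for the C++ core)
lattice_edges <- function(side) {
  from <- integer(0); to <- integer(0)
  for (r in 0:(side - 1)) for (c in 0:(side - 1)) {
    n <- r * side + c
    if (c < side - 1) { from <- c(from, n); to <- c(to, n + 1L) }
    if (r < side - 1) { from <- c(from, n); to <- c(to, n + side) }
  }
  list(from = as.integer(from), to = as.integer(to))
}

# Fixed constants of the surrogate dynamics (dimensionless membrane,
# threshold 1).  Chosen once to give ~1-2 Hz irregular firing with a
# ~5 Hz subthreshold oscillation, a firing rate that falls with g_i and
# pairwise synchrony that rises with g_c; see the methods vignette.
surrogate_constants <- function() {
  list(osc_hz = 4,       # subthreshold oscillation frequency
       damp = 0.8,       # oscillator damping (1/s)
       b0 = 0.50,        # baseline depolarization at g_i = g_e = 0
       k_e = 4,          # excitatory gain  (baseline += k_e * g_e)
       k_i = 0.08,       # inhibitory gain  (baseline -= k_i * g_i)
       gc_gain = 0.4,    # diffusive coupling per unit g_c per edge (1/s)
       kick = 0.12,      # spikelet depolarization per unit g_c per edge
       sd_x = 0.10,      # independent slow membrane noise (per sqrt(s))
       sd_shared = 0.22, # shared afferent drive on the slow component
       sd_u = 0.25,      # recovery noise
       sd_z = 0.45,      # fast OU synaptic noise
       tau_z = 0.015,    # fast-noise time constant (s)
       x_reset = -0.35,  # post-spike reset of the membrane deviation
       refrac_s = 0.02)  # absolute refractory period
}

#' Simulate the surrogate coupled network at one (g_i, g_c)
#'
#' A lattice of conductance-based noisy subthreshold oscillators stands
#' in for the biophysical olivary network: `g_i` hyperpolarizes the
#' baseline (lowering firing rate), `g_c` couples neighbouring membrane
#' potentials diffusively (raising spike synchrony).  Identical seeds
#' give identical spike trains.
#'
#' @param g_i inhibitory conductance (mS/cm2), >= 0.
#' @param g_c gap-junctional conductance (mS/cm2), >= 0.
#' @param cfg a [sim_config()].
#' @return a [spike_train_set()] with condition `"SIM"` and the
#'   generating parameters in `metadata`.
#' @export
simulate_network <- function(g_i, g_c, cfg = sim_config()) {
  stopifnot(g_i >= 0, g_c >= 0)
  cst <- surrogate_constants()
  side <- as.integer(round(sqrt(cfg$n_neurons)))
  max_deg <- if (side > 1) 4 else 0
  # explicit Euler stability guard for the stiffest linear rate
  if (cfg$dt * (cst$damp + cst$gc_gain * g_c * max_deg +
                2 * pi * cst$osc_hz) > 0.5)
    stop("time step dt is numerically unstable here; use a smaller dt")
  set.seed(cfg$noise_seed)
  frac <- cfg$heterogeneity_frac
  # heterogeneity on the oscillatory conductance (g_CaL stand-in) and on
  # the per-edge gap-junction strength
  omega <- 2 * pi * cst$osc_hz *
    sample_heterogeneity(1, frac, cfg$n_neurons)
  edges <- lattice_edges(side)
  ew <- sample_heterogeneity(1, frac, length(edges$from))
  baseline <- rep(cst$b0 + cst$k_e * cfg$g_e - cst$k_i * g_i,
                  cfg$n_neurons)
  n_steps <- as.integer(round(cfg$duration / cfg$dt))
  sp <- sim_network_cpp(cfg$n_neurons, n_steps, cfg$dt,
                        baseline, omega, cst$damp,
                        cst$gc_gain * g_c, cst$kick * g_c,
                        edges$from, edges$to, ew,
                        cst$sd_x, cst$sd_shared, cst$sd_u,
                        cst$sd_z, cst$tau_z, cst$x_reset, cst$refrac_s)
  trains <- lapply(seq_along(sp), function(i)
    spike_train(sp[[i]], cfg$duration, sprintf("sim%02d", i)))
  spike_train_set(trains, "SIM",
                  metadata = list(g_i = g_i, g_c = g_c,
                                  noise_seed = cfg$noise_seed))
}

#' Simulate a library of realizations over a whole parameter grid
#'
#' Per-cell seeds are derived deterministically from the cell index and
#' `cfg$noise_seed`, so the library is reproducible and independent of
#' evaluation order.
#'
#' @param grid a [parameter_grid()].
#' @param cfg a [sim_config()]; its `noise_seed` acts as the base seed.
#' @param n_realizations independent runs per grid cell.
#' @return object of class `sim_library`: fields `grid`, `cells` (list
#'   with `gi`, `gc`, `sets`), `n_realizations`.
#' @export
run_grid_simulation <- function(grid, cfg = sim_config(),
                                n_realizations = 3L) {
  cells <- grid_cells(grid)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    sets <- lapply(seq_len(n_realizations), function(r) {
      cfg_r <- cfg
      cfg_r$noise_seed <- derive_seed(cfg$noise_seed, (ci - 1L) * 1000L + r)
      simulate_network(cells$gi[ci], cells$gc[ci], cfg_r)
    })
    out[[ci]] <- list(gi = cells$gi[ci], gc = cells$gc[ci], sets = sets)
  }
  structure(list(grid = grid, cells = out,
                 n_realizations = as.integer(n_realizations), cfg = cfg),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim_library> %d cells x %d realizations of %.0f s\n",
              length(x$cells), x$n_realizations, x$cfg$duration))
  invisible(x)
}

#' Persist a simulation library as one spike CSV per realization plus a
#' JSON manifest
#'
#' @param lib a `sim_library` from [run_grid_simulation()].
#' @param dir directory to create.
#' @return `dir`, invisibly.
#' @export
save_sim_library <- function(lib, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (ci in seq_along(lib$cells)) {
    cell <- lib$cells[[ci]]
    cdir <- file.path(dir, sprintf("gi%.3f_gc%.3f", cell$gi, cell$gc))
    dir.create(cdir, showWarnings = FALSE)
    for (r in seq_along(cell$sets))
      write_spike_trains(cell$sets[[r]],
                         file.path(cdir, sprintf("real%03d.csv", r)))
    files[[ci]] <- list(gi = cell$gi, gc = cell$gc, dir = basename(cdir))
  }
  manifest <- list(grid = list(gi_values = lib$grid$gi_values,
                               gc_values = lib$grid$gc_values,
                               step = lib$grid$step),
                   n_realizations = lib$n_realizations,
                   cfg = unclass(lib$cfg), cells = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a simulation library saved by [save_sim_library()]
#' @param dir directory holding `manifest.json`.
#' @return a `sim_library`.
#' @export
load_sim_library <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  g <- manifest$grid
  grid <- parameter_grid(range(g$gi_values), range(g$gc_values), g$step)
  cfg <- do.call(sim_config, manifest$cfg[names(manifest$cfg) != "class"])
  cells <- lapply(seq_len(nrow(manifest$cells)), function(ci) {
    row <- manifest$cells[ci, ]
    cdir <- file.path(dir, row$dir)
    sets <- lapply(sort(list.files(cdir, pattern = "^real.*\\.csv$",
                                   full.names = TRUE)),
                   read_spike_trains)
    list(gi = row$gi, gc = row$gc, sets = sets)
  })
  structure(list(grid = grid, cells = cells,
                 n_realizations = manifest$n_realizations, cfg = cfg),
            class = "sim_library")
}
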