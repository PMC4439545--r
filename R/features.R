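#' Names of the 68 segment features, in canonical order
#'
#' Block structure: FR (1), LV (1), ACG1-20, CCG1-20, MD1-25, SD (1).
#' @return character vector of length 68.
#' @export
feature_names <- function() {
  c("fr", "lv",
    sprintf("acg%02d", 1:20), sprintf("ccg%02d", 1:20),
    sprintf("md%02d", 1:25), "sd")
}

#' Mean firing rate of a train within a segment
#'
#' @param seg a segment row (list/data.frame row with `t_start`, `t_end`).
#' @param tr a [spike_train()].
#' @return rate in Hz (spike count divided by segment length).
#' @export
firing_rate <- function(seg, tr) {
  length(spikes_in_window(tr, seg$t_start, seg$t_end)) /
    (seg$t_end - seg$t_start)
}

#' Local variation of an inter-spike-interval sequence
#'
#' \deqn{LV = \frac{1}{R-1}\sum_{r=1}^{R-1}
#'       \frac{3 (T_{r+1}-T_r)^2}{(T_{r+1}+T_r)^2}}
#' A pure ratio statistic: 0 for a perfectly regular train, about 1 for
#' Poisson firing, approaching 3 for extreme burstiness.
#'
#' @param isis ordered inter-spike intervals (seconds), all positive.
#' @return LV, or `NA` (undefined-feature sentinel) with fewer than two
#'   ISIs.
#' @export
local_variation <- function(isis) {
  if (length(isis) < 2L) return(feature_sentinel())
  stopifnot(all(isis > 0))
  a <- isis[-length(isis)]; b <- isis[-1L]
  mean(3 * (b - a)^2 / (b + a)^2)
}

#' Autocorrelogram of a train within a segment
#'
#' Counts ordered spike pairs with lag in each of 20 bins of 50 ms
#' spanning 0-1000 ms, excluding zero-lag self pairs.  By default counts
#' are divided by the spike count of the train so segments of different
#' rate are comparable; `normalize = FALSE` gives raw pair counts.
#'
#' @param tr a [spike_train()].
#' @param seg segment row with `t_start`, `t_end`.
#' @param bin bin width in seconds (default 0.05).
#' @param max_delay maximum lag in seconds (default 1).
#' @param normalize divide counts by the number of spikes?
#' @return numeric vector of `max_delay / bin` values.
#' @export
autocorrelogram <- function(tr, seg, bin = 0.05, max_delay = 1,
                            normalize = TRUE) {
  k <- max_delay / bin
  stopifnot(abs(k - round(k)) < 1e-9)
  ts <- spikes_in_window(tr, seg$t_start, seg$t_end)
  counts <- lag_counts(ts, ts, bin, max_delay, TRUE)
  if (normalize && length(ts)) counts <- counts / length(ts)
  counts
}

# clean O(n log n + pairs) lag binning used by ACG/CCG
lag_counts <- function(t_ref, t_other, bin, max_delay, exclude_self) {
  n_bins <- as.integer(round(max_delay / bin))
  counts <- numeric(n_bins)
  if (!length(t_ref) || !length(t_other)) return(counts)
  to <- sort(t_other)
  for (tl in t_ref) {
    i1 <- findInterval(tl - max_delay, to, left.open = TRUE) + 1L
    i2 <- findInterval(tl, to)
    if (i2 < i1) next
    lag <- tl - to[i1:i2]
    if (exclude_self) lag <- lag[lag > 0]
    # exclude lags equal to max_delay boundary artifacts
    lag <- lag[lag < max_delay]
    if (length(lag))
      counts <- counts + tabulate(floor(lag / bin) + 1L, nbins = n_bins)
  }
  counts
}

#' Crosscorrelogram between two trains within a segment
#'
#' Counts ordered pairs with lag `t_i - t_j` in 20 bins of 50 ms over
#' 0-1000 ms; zero-lag coincidences are included.  Normalized by the
#' spike count of the reference train `tr_i` unless `normalize = FALSE`.
#'
#' @inheritParams autocorrelogram
#' @param tr_i reference train (its spikes index the lags).
#' @param tr_j comparison train.
#' @return numeric vector of `max_delay / bin` values.
#' @export
crosscorrelogram <- function(tr_i, tr_j, seg, bin = 0.05, max_delay = 1,
                             normalize = TRUE) {
  ti <- spikes_in_window(tr_i, seg$t_start, seg$t_end)
  tj <- spikes_in_window(tr_j, seg$t_start, seg$t_end)
  counts <- lag_counts(ti, tj, bin, max_delay, FALSE)
  if (normalize && length(ti)) counts <- counts / length(ti)
  counts
}

#' Minimal-distance histogram between two trains
#'
#' For each spike `l` of train `i` the nearest-spike statistic
#' \deqn{s_l = 1 - \exp(-2 \min_m |t_l^i - t_m^j| / \bar d_j)}
#' is computed, where \eqn{\bar d_j} is the mean ISI of train `j`.  For
#' independent Poisson firing the `s_l` are uniform on \[0, 1\]; tight
#' synchrony piles mass near 0.  The histogram over 25 equal bins is
#' normalized to sum 1.
#'
#' @param tr_i,tr_j [spike_train()]s (or plain numeric spike-time
#'   vectors) already restricted to a common window.
#' @param n_bins number of histogram bins (default 25).
#' @return numeric vector of `n_bins` fractions summing to 1, or
#'   sentinel `NA`s if either train is too sparse (no spikes in `i`, or
#'   fewer than 2 spikes in `j` so \eqn{\bar d_j} is undefined).
#' @export
minimal_distance_histogram <- function(tr_i, tr_j, n_bins = 25L) {
  ti <- if (inherits(tr_i, "spike_train")) tr_i$times else as.numeric(tr_i)
  tj <- if (inherits(tr_j, "spike_train")) tr_j$times else as.numeric(tr_j)
  if (!length(ti) || length(tj) < 2L) return(rep(feature_sentinel(), n_bins))
  dbar <- mean(diff(sort(tj)))
  if (dbar <= 0) return(rep(feature_sentinel(), n_bins))
  tj <- sort(tj)
  pos <- findInterval(ti, tj)
  d_left <- ifelse(pos >= 1L, ti - tj[pmax(pos, 1L)], Inf)
  d_right <- ifelse(pos < length(tj), tj[pmin(pos + 1L, length(tj))] - ti, Inf)
  dmin <- pmin(d_left, d_right)
  s <- 1 - exp(-2 * dmin / dbar)
  idx <- pmin(floor(s * n_bins) + 1L, n_bins)  # right-closed last bin
  tabulate(idx, nbins = n_bins) / length(s)
}

#' SPIKE-distance between two trains within a segment
#'
#' The adaptive, parameter-free spike-train dissimilarity: a
#' piecewise-linear instantaneous profile S(t) built from the distances
#' of the bracketing spikes of each train to their nearest counterparts
#' in the other train, weighted by the local inter-spike intervals, is
#' averaged over the segment.  Values lie in \[0, 1\]; 0 iff the two
#' trains are identical.  Auxiliary spikes at the segment edges provide
#' the standard edge correction.
#'
#' @param tr_i,tr_j [spike_train()]s or numeric spike-time vectors.
#' @param seg segment row with `t_start`, `t_end` (default: full
#'   recording of `tr_i` when it is a `spike_train`).
#' @return the time-averaged SPIKE-distance, or sentinel `NA` when
#'   either train has no spike in the segment.
#' @export
spike_distance <- function(tr_i, tr_j, seg = NULL) {
  ti <- if (inherits(tr_i, "spike_train")) tr_i$times else as.numeric(tr_i)
  tj <- if (inherits(tr_j, "spike_train")) tr_j$times else as.numeric(tr_j)
  if (is.null(seg)) {
    stopifnot(inherits(tr_i, "spike_train"))
    seg <- list(t_start = 0, t_end = tr_i$duration)
  }
  t0 <- seg$t_start; t1 <- seg$t_end
  ti <- ti[ti >= t0 & ti < t1] - t0
  tj <- tj[tj >= t0 & tj < t1] - t0
  if (!length(ti) || !length(tj)) return(feature_sentinel())
  TT <- t1 - t0
  spike_distance_profile_mean(ti, tj, TT)
}

# core SPIKE-distance computation on [0, TT]; trains assumed sorted
spike_distance_profile_mean <- function(ti, tj, TT) {
  aug <- function(x) {
    x <- sort(x)
    if (x[1] > 0) x <- c(0, x)
    if (x[length(x)] < TT) x <- c(x, TT)
    x
  }
  a <- aug(ti); b <- aug(tj)
  nn_dist <- function(x, ref) {
    pos <- findInterval(x, ref)
    dl <- ifelse(pos >= 1L, x - ref[pmax(pos, 1L)], Inf)
    dr <- ifelse(pos < length(ref), ref[pmin(pos + 1L, length(ref))] - x, Inf)
    pmin(dl, dr)
  }
  da <- nn_dist(a, b)  # distance of each spike of a to nearest spike of b
  db <- nn_dist(b, a)
  # merged breakpoints; S(t) is linear between consecutive breakpoints
  brk <- sort(unique(c(a, b)))
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  len <- diff(brk)
  s_at <- function(t) {
    pa <- findInterval(t, a)          # a[pa] <= t < a[pa+1]
    pa <- pmin(pmax(pa, 1L), length(a) - 1L)
    pb <- findInterval(t, b)
    pb <- pmin(pmax(pb, 1L), length(b) - 1L)
    xisi1 <- a[pa + 1L] - a[pa]
    xisi2 <- b[pb + 1L] - b[pb]
    s1 <- (da[pa] * (a[pa + 1L] - t) + da[pa + 1L] * (t - a[pa])) / xisi1
    s2 <- (db[pb] * (b[pb + 1L] - t) + db[pb + 1L] * (t - b[pb])) / xisi2
    m <- (xisi1 + xisi2) / 2
    (s1 * xisi2 + s2 * xisi1) / (2 * m^2)
  }
  sum(s_at(mids) * len) / TT
}

#' Assemble the 68-component feature vector of one segment
#'
#' Per-neuron features (FR, LV, ACG) are averaged over the three
#' neurons; pairwise features (CCG, MD, SD) are averaged over the three
#' unordered pairs, with the direction-asymmetric CCG and MD averaged
#' over both orders within a pair first (so the vector is invariant to
#' permuting the neurons).  Any undefined sub-feature propagates as `NA`
#' and flags the vector.
#'
#' @param trains list of exactly 3 [spike_train()]s.
#' @param seg segment row with `t_start`, `t_end`.
#' @param normalize_correlograms divide correlogram counts by spike
#'   counts (default `TRUE`)?
#' @return named numeric vector of length 68 (see [feature_names()]),
#'   with attribute `flagged = TRUE` if any component is the sentinel.
#' @export
compute_feature_vector <- function(trains, seg,
                                   normalize_correlograms = TRUE) {
  stopifnot(length(trains) == 3L)
  win <- lapply(trains, spikes_in_window,
                t_start = seg$t_start, t_end = seg$t_end)
  fr <- mean(vapply(trains, function(tr) firing_rate(seg, tr), numeric(1)))
  lv <- mean(vapply(win, function(ts) local_variation(diff(ts)), numeric(1)))
  acg <- rowMeans(vapply(trains, autocorrelogram, numeric(20), seg = seg,
                         normalize = normalize_correlograms))
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  ccg <- rowMeans(vapply(pairs, function(p) {
    (crosscorrelogram(trains[[p[1]]], trains[[p[2]]], seg,
                      normalize = normalize_correlograms) +
     crosscorrelogram(trains[[p[2]]], trains[[p[1]]], seg,
                      normalize = normalize_correlograms)) / 2
  }, numeric(20)))
  md <- rowMeans(vapply(pairs, function(p) {
    (minimal_distance_histogram(win[[p[1]]], win[[p[2]]]) +
     minimal_distance_histogram(win[[p[2]]], win[[p[1]]])) / 2
  }, numeric(25)))
  sd_ <- mean(vapply(pairs, function(p)
    spike_distance(trains[[p[1]]], trains[[p[2]]], seg = seg), numeric(1)))
  fv <- c(fr, lv, acg, ccg, md, sd_)
  names(fv) <- feature_names()
  attr(fv, "flagged") <- anyNA(fv)
  fv
}

#' Kolmogorov-Smirnov distance of an ISI sample to the matched Poisson
#' (exponential) model
#'
#' A non-stationarity / irregularity metric: the sup difference between
#' the empirical ISI distribution and an exponential distribution with
#' the same mean.
#'
#' @param isis inter-spike intervals (>= 2 values).
#' @return KS distance in \[0, 1\].
#' @export
ks_distance_to_poisson <- function(isis) {
  stopifnot(length(isis) >= 2L)
  x <- sort(isis)
  n <- length(x)
  fx <- stats::pexp(x, rate = 1 / mean(x))
  max(abs(seq_len(n) / n - fx), abs((seq_len(n) - 1) / n - fx))
}

#' Standard deviation of the windowed firing rate
#'
#' @param tr a [spike_train()].
#' @param window window length in seconds.
#' @return SD (Hz) of the per-window rate estimates across the
#'   recording (tail shorter than one window is dropped).
#' @export
firing_rate_sd <- function(tr, window) {
  stopifnot(window > 0)
  n_win <- floor(tr$duration / window + 1e-9)
  if (n_win < 1L) stop("window longer than the recording")
  idx <- pmin(floor(tr$times / window) + 1L, n_win)
  idx <- idx[tr$times < n_win * window]
  rates <- tabulate(idx, nbins = n_win) / window
  stats::sd(rates)
}
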