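#' Spike-train containers
#'
#' A `spike_train` is an ordered vector of spike times (seconds) on
#' `[0, duration]` belonging to one neuron.  Times are stored at a fixed
#' resolution of 0.1 ms: finer than any feature bin used downstream
#' (50 ms) but coarse enough that text round-trips are exact.
#'
#' @param times numeric vector of spike times in seconds.
#' @param duration recording duration in seconds.
#' @param neuron_id label for the neuron.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, duration, neuron_id = "n1") {
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0)
  times <- round(as.numeric(times), 4L)  # 0.1 ms resolution
  if (is.unsorted(times)) times <- sort(times)
  if (length(times) && (min(times) < 0 || max(times) > duration))
    stop("spike times must lie in [0, duration]; offending train: ", neuron_id)
  if (anyDuplicated(times))
    stop("duplicate spike times at 0.1 ms resolution in train: ", neuron_id)
  structure(
    list(times = times, duration = as.numeric(duration),
         neuron_id = as.character(neuron_id)),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes over %.1f s (%.3f Hz)\n",
              x$neuron_id, length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

#' Multi-neuron recording under one experimental condition
#'
#' @param trains list of [spike_train()] objects sharing one duration.
#' @param condition one of `"CON"`, `"PIX"`, `"CBX"`, `"SIM"`.
#' @param metadata free-form named list.
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, condition = "SIM", metadata = list()) {
  condition <- match.arg(condition, c("CON", "PIX", "CBX", "SIM"))
  stopifnot(length(trains) >= 1L,
            all(vapply(trains, inherits, logical(1), "spike_train")))
  durs <- vapply(trains, `[[`, numeric(1), "duration")
  if (length(unique(durs)) != 1L)
    stop("all trains in a spike_train_set must share one duration")
  structure(
    list(trains = trains, condition = condition,
         duration = durs[[1L]], metadata = metadata),
    class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %s: %d neurons, %.1f s, %d spikes total\n",
              x$condition, length(x$trains), x$duration,
              sum(vapply(x$trains, function(tr) length(tr$times), integer(1)))))
  invisible(x)
}

n_spikes <- function(s) {
  sum(vapply(s$trains, function(tr) length(tr$times), integer(1)))
}

#' Read a spike recording from its plain-text format
#'
#' The format is CSV with commented header lines declaring the recording
#' duration, condition and the full set of neuron ids (so that silent
#' neurons survive a round-trip), followed by `neuron_id,time_s` rows:
#' ```
#' # duration_s=500
#' # condition=CON
#' # neurons=n1,n2,n3
#' neuron_id,time_s
#' n1,0.4310
#' ```
#'
#' @param path file to read.
#' @return a [spike_train_set()].
#' @export
read_spike_trains <- function(path) {
  if (!file.exists(path)) stop("no such spike file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (!length(hit)) stop("spike file header missing '", key, "=': ", path)
    sub(paste0("^#\\s*", key, "=\\s*"), "", hit[[1L]])
  }
  duration <- as.numeric(get_field("duration_s"))
  if (!is.finite(duration)) stop("unparseable duration_s header in ", path)
  condition <- get_field("condition")
  neuron_ids <- strsplit(get_field("neurons"), ",", fixed = TRUE)[[1L]]

  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) && identical(body[[1L]], "neuron_id,time_s"))
    body <- body[-1L]
  ids <- character(length(body)); tms <- numeric(length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(body[[i]], ",", fixed = TRUE)[[1L]]
    tm <- suppressWarnings(as.numeric(parts[2L]))
    if (length(parts) != 2L || is.na(tm))
      stop(sprintf("malformed spike row at line %d of %s: '%s'",
                   which(lines == body[[i]])[1L], path, body[[i]]))
    ids[i] <- parts[1L]; tms[i] <- tm
  }
  if (length(tms) && (any(tms < 0) || any(tms > duration)))
    stop("spike time outside [0, duration] in ", path)
  if (!all(ids %in% neuron_ids))
    stop("row neuron_id not declared in '# neurons=' header: ",
         paste(setdiff(ids, neuron_ids), collapse = ", "))
  trains <- lapply(neuron_ids, function(id)
    spike_train(tms[ids == id], duration, id))
  spike_train_set(trains, condition)
}

#' Write a spike recording in the plain-text format of [read_spike_trains()]
#'
#' Times are formatted at the package's fixed 0.1 ms resolution, so
#' `read_spike_trains(write_spike_trains(s, f))` reproduces `s` exactly.
#'
#' @param s a [spike_train_set()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(s, path) {
  stopifnot(inherits(s, "spike_train_set"))
  ids <- vapply(s$trains, `[[`, character(1), "neuron_id")
  hdr <- c(sprintf("# duration_s=%s", format(s$duration, scientific = FALSE)),
           sprintf("# condition=%s", s$condition),
           sprintf("# neurons=%s", paste(ids, collapse = ",")),
           "neuron_id,time_s")
  rows <- unlist(lapply(s$trains, function(tr)
    if (length(tr$times)) sprintf("%s,%.4f", tr$neuron_id, tr$times)
    else character(0)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Cut a recording into contiguous fixed-length segments
#'
#' Segments are half-open intervals `[t_start, t_end)` so that boundary
#' spikes are never double-counted.  A duration that is not an integer
#' multiple of `seg_len` is tail-truncated with a warning.
#'
#' @param s a [spike_train_set()] (or a single [spike_train()]).
#' @param seg_len segment length in seconds (default 50).
#' @return a data.frame with columns `index`, `t_start`, `t_end`, one row
#'   per segment.
#' @export
segment_recording <- function(s, seg_len = 50) {
  stopifnot(seg_len > 0)
  duration <- s$duration
  if (seg_len > duration) stop("seg_len exceeds the recording duration")
  n_seg <- floor(duration / seg_len + 1e-9)
  if (abs(n_seg * seg_len - duration) > 1e-9)
    warning(sprintf("duration %.4g s is not a multiple of seg_len %.4g s; %.4g s truncated",
                    duration, seg_len, duration - n_seg * seg_len))
  data.frame(index = seq_len(n_seg),
             t_start = (seq_len(n_seg) - 1) * seg_len,
             t_end = seq_len(n_seg) * seg_len)
}

#' Spikes of one train falling in a half-open window
#' @keywords internal
spikes_in_window <- function(tr, t_start, t_end) {
  tr$times[tr$times >= t_start & tr$times < t_end]
}

#' Bin a spike train into fixed-width count bins
#'
#' @param tr a [spike_train()].
#' @param window numeric length-2, half-open window `[t0, t1)` in seconds.
#' @param bin_width bin width in seconds.
#' @return an object of class `binned_spikes` with fields `counts`,
#'   `bin_width`, `n_bins`.  Bin `k` (1-based) covers
#'   `[t0 + (k-1) w, t0 + k w)`; the total count equals the number of
#'   spikes in the window.
#' @export
bin_spikes <- function(tr, window, bin_width) {
  stopifnot(bin_width > 0, length(window) == 2L, window[2] > window[1])
  t0 <- window[1]; t1 <- window[2]
  n_bins <- as.integer(ceiling((t1 - t0) / bin_width - 1e-12))
  ts <- spikes_in_window(tr, t0, t1)
  idx <- pmin(floor((ts - t0) / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(counts = counts, bin_width = bin_width, n_bins = n_bins),
            class = "binned_spikes")
}
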