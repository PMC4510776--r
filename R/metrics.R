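## Spike-log metrics: dopamine burst/dip detection, traveling-wave scoring,
## weight maps.

#' Detect dopaminergic population bursts
#'
#' Population spike counts are taken in sliding 50-ms bins (stepped by
#' `bin_step_ms`); a burst is a maximal run of bins exceeding
#' `baseline mean + 3 SD`, and runs separated by less than the merge gap
#' are joined.  The baseline statistics are estimated from the pre-stimulus
#' segment `baseline_window`.
#'
#' @param spike_times numeric vector of dopaminergic spike times (ms)
#' @param trial_window `c(start, end)` ms in which to search for bursts
#' @param baseline_window `c(start, end)` ms used to estimate the baseline;
#'   if `NULL`, `baseline_mean`/`baseline_sd` must be given
#' @param bin_ms sliding-bin width (default 50)
#' @param bin_step_ms bin step (default 10)
#' @param merge_gap_ms runs closer than this are merged (default 200)
#' @param baseline_mean,baseline_sd optional externally supplied baseline
#'   bin statistics
#' @param min_count bursts additionally require at least this many spikes
#'   in a bin (guards against a zero-variance silent baseline; default 5)
#' @return an object of class `burst_report`: list with `bursts`
#'   (data.frame `start`, `end`), `classification` (`"none"`, `"single"`,
#'   `"multiple"`), `baseline_mean`, `baseline_sd`, `threshold`
#' @export
detect_da_bursts <- function(spike_times, trial_window,
                             baseline_window = NULL,
                             bin_ms = 50, bin_step_ms = 10,
                             merge_gap_ms = 200,
                             baseline_mean = NULL, baseline_sd = NULL,
                             min_count = 5) {
  spike_times <- sort(as.numeric(spike_times))
  if (is.null(baseline_mean)) {
    stopifnot(!is.null(baseline_window))
    bs <- sliding_counts(spike_times, baseline_window, bin_ms, bin_step_ms)
    baseline_mean <- mean(bs$count)
    baseline_sd <- stats::sd(bs$count)
    if (!is.finite(baseline_sd)) baseline_sd <- 0
  }
  threshold <- max(baseline_mean + 3 * baseline_sd, min_count)
  sc <- sliding_counts(spike_times, trial_window, bin_ms, bin_step_ms)
  hot <- sc$count > threshold
  runs <- run_intervals(sc$start[hot], sc$start[hot] + bin_ms, merge_gap_ms)
  classification <- if (nrow(runs) == 0) "none"
                    else if (nrow(runs) == 1) "single" else "multiple"
  structure(list(bursts = runs, classification = classification,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 threshold = threshold),
            class = "burst_report")
}

sliding_counts <- function(times, window, bin_ms, step_ms) {
  starts <- seq(window[1], max(window[1], window[2] - bin_ms), by = step_ms)
  counts <- vapply(starts, function(s) {
    sum(times >= s & times < s + bin_ms)
  }, numeric(1))
  list(start = starts, count = counts)
}

## merge [start, end) intervals whose gaps are below merge_gap
run_intervals <- function(starts, ends, merge_gap) {
  if (length(starts) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]
  res_s <- numeric(0); res_e <- numeric(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - out_e < merge_gap) {
      out_e <- max(out_e, ends[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- starts[i]; out_e <- ends[i]
    }
  }
  data.frame(start = c(res_s, out_s), end = c(res_e, out_e))
}

#' Longest dopamine-free interval in a window
#'
#' Returns the duration (ms) of the longest interval containing no
#' dopaminergic spikes inside `search_window`, counting the edges of the
#' window as interval boundaries.
#'
#' @param spike_times dopaminergic spike times (ms)
#' @param search_window `c(start, end)` ms
#' @return the maximal spike-free gap (ms)
#' @export
detect_da_dip <- function(spike_times, search_window) {
  inside <- sort(spike_times[spike_times >= search_window[1] &
                               spike_times <= search_window[2]])
  pts <- c(search_window[1], inside, search_window[2])
  max(diff(pts))
}

#' Score a traveling-wave probe trial
#'
#' A probe fails when the rightmost (edge) columns emit no spikes inside
#' the expected arrival window.  Ghost activity is counted as the number of
#' suprathreshold edge-column episodes (at least `ghost_min_spikes` spikes
#' within any 50-ms bin, adjacent bins merged) outside the window.
#'
#' @param times spike times (ms) of the excitatory sheet
#' @param cols x-coordinate (column) of each spike
#' @param expected_window `c(start, end)` ms, default `c(1950, 2050)`
#' @param edge_cols columns that count as the right edge, default
#'   `508:511`
#' @param trial_ms trial length for ghost scanning (default 2500)
#' @param ghost_min_spikes episode threshold (default 2 spikes / 50 ms)
#' @return an object of class `wave_outcome`: list with `ok`, `ghosts`,
#'   `latency_ms` (first suprathreshold edge activity, `NA` on fail)
#' @export
wave_outcome <- function(times, cols, expected_window = c(1950, 2050),
                         edge_cols = 508:511, trial_ms = 2500,
                         ghost_min_spikes = 2) {
  edge_t <- sort(times[cols %in% edge_cols])
  ok <- any(edge_t >= expected_window[1] & edge_t <= expected_window[2])
  ## suprathreshold episodes over the whole trial
  sc <- sliding_counts(edge_t, c(0, trial_ms), 50, 10)
  hot <- sc$count >= ghost_min_spikes
  runs <- run_intervals(sc$start[hot], sc$start[hot] + 50, 50)
  ghosts <- 0L
  latency <- NA_real_
  if (nrow(runs) > 0) {
    in_win <- runs$end > expected_window[1] & runs$start < expected_window[2]
    ghosts <- sum(!in_win)
    first_edge <- edge_t[edge_t >= runs$start[1]]
    if (length(first_edge)) latency <- first_edge[1]
  }
  structure(list(ok = ok, ghosts = as.integer(ghosts), latency_ms = latency),
            class = "wave_outcome")
}

#' Per-pre-neuron summed outgoing weight, arranged on the pre layout
#'
#' @param projection a realized projection (list with 0-based `pre`, `w`)
#' @param layout `c(width, height)` of the pre group grid
#' @return a `height x width` matrix; entry `[y+1, x+1]` is the summed
#'   outgoing weight of the pre neuron at grid position `(x, y)` (row-major
#'   indexing `x + y * width`)
#' @export
weight_map <- function(projection, layout) {
  width <- layout[1]; height <- layout[2]
  m <- matrix(0, nrow = height, ncol = width)
  if (length(projection$pre)) {
    sums <- tapply(projection$w, projection$pre, sum)
    idx <- as.integer(names(sums))
    m[cbind(idx %/% width + 1L, idx %% width + 1L)] <- as.numeric(sums)
  }
  m
}
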