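## Synthetic trackball hand sweeps and their spike encodings.
##
## The generator reproduces the measured statistics of human hand sweeps
## across a 9-by-8 trackball grid: per-direction-class Gaussians for contact
## duration, speed, event count and direction-noise level, with 4-7
## trackballs touched simultaneously.  Events are placed along the swept
## path so that grid position is monotone in time.

GRID_NCOL <- 9L  # x in 0..8
GRID_NROW <- 8L  # y in 0..7
DIRECTIONS <- c("up", "down", "left", "right")

#' Measured sweep statistics by direction class
#'
#' `(mean, sd)` pairs for contact duration (ms), speed (inch/s), touch-event
#' count, and direction-noise level (percent), for the vertical (up/down)
#' and horizontal (left/right) sweep classes.  Horizontal sweeps last
#' longer, carry more events and are noisier because the trackballs are
#' aligned along columns rather than rows.
#'
#' @format a list with elements `vertical` and `horizontal`, each a list of
#'   `duration_ms`, `speed_in_s`, `n_events`, `noise_pct` two-vectors
#' @export
SWEEP_STATS <- list(
  vertical = list(duration_ms = c(935, 142), speed_in_s = c(7.3, 1.08),
                  n_events = c(207, 44), noise_pct = c(8.31, 3.97)),
  horizontal = list(duration_ms = c(1071, 128), speed_in_s = c(6.73, 0.93),
                    n_events = c(305, 69), noise_pct = c(19.72, 5.53))
)

direction_class <- function(direction) {
  if (direction %in% c("up", "down")) "vertical" else "horizontal"
}

rtruncnorm_pos <- function(n, mean, sd, floor = 0) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= floor)) {
    bad <- x <= floor
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Sample one synthetic hand sweep
#'
#' Draws duration, speed, event count and noise level from the
#' direction-class Gaussians in [SWEEP_STATS] (truncated at zero, counts
#' rounded), samples a footprint of 4-7 simultaneously touched trackballs,
#' distributes the events along the swept path over the duration, and
#' reassigns the noise fraction of events uniformly to the other three
#' directions.  The realized noise level follows the measured definition:
#' events in unintended directions divided by events in the intended
#' direction.
#'
#' Uses the R random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param direction one of `"up"`, `"down"`, `"left"`, `"right"`
#' @param noise_override if not `NULL`, force this noise level (fraction,
#'   e.g. 0 for a clean sweep)
#' @return an object of class `sweep_record`: list with `direction`,
#'   `duration_ms`, `speed_in_s`, `footprint`, `noise_level` (realized
#'   fraction) and `events`, a data.frame with columns `x`, `y`,
#'   `direction`, `t` (ms from sweep onset)
#' @export
sample_sweep <- function(direction = c("up", "down", "left", "right"),
                         noise_override = NULL) {
  direction <- match.arg(direction)
  cls <- SWEEP_STATS[[direction_class(direction)]]
  duration <- rtruncnorm_pos(1, cls$duration_ms[1], cls$duration_ms[2])
  speed <- rtruncnorm_pos(1, cls$speed_in_s[1], cls$speed_in_s[2])
  n_events <- max(1L, as.integer(round(
    rtruncnorm_pos(1, cls$n_events[1], cls$n_events[2]))))
  noise <- if (is.null(noise_override)) {
    max(0, stats::rnorm(1, cls$noise_pct[1], cls$noise_pct[2])) / 100
  } else {
    noise_override
  }
  footprint <- sample(4:7, 1)

  ## Path: the footprint band sweeps along the movement axis; position on
  ## the axis is monotone in time, position across it is uniform inside the
  ## band.
  tt <- sort(stats::runif(n_events, 0, duration))
  progress <- tt / duration
  if (direction %in% c("up", "down")) {
    axis_n <- GRID_NROW
    band <- seq(sample.int(GRID_NCOL - footprint + 1, 1) - 1L,
                length.out = footprint)
    pos <- as.integer(pmin(floor(progress * axis_n), axis_n - 1L))
    y <- if (direction == "down") pos else (axis_n - 1L - pos)
    x <- sample(band, n_events, replace = TRUE)
  } else {
    axis_n <- GRID_NCOL
    band <- seq(sample.int(GRID_NROW - footprint + 1, 1) - 1L,
                length.out = footprint)
    pos <- as.integer(pmin(floor(progress * axis_n), axis_n - 1L))
    x <- if (direction == "right") pos else (axis_n - 1L - pos)
    y <- sample(band, n_events, replace = TRUE)
  }

  dirs <- rep(direction, n_events)
  ## noise = unintended / intended  =>  flip k of n with k/(n-k) = noise
  k <- round(n_events * noise / (1 + noise))
  if (k > 0) {
    flip <- sample.int(n_events, k)
    dirs[flip] <- sample(setdiff(DIRECTIONS, direction), k, replace = TRUE)
  }
  realized <- sum(dirs != direction) / max(1L, sum(dirs == direction))

  events <- data.frame(x = as.integer(x), y = as.integer(y),
                       direction = dirs, t = tt)
  structure(list(direction = direction, duration_ms = duration,
                 speed_in_s = speed, footprint = footprint,
                 noise_level = realized, events = events),
            class = "sweep_record")
}

#' @export
print.sweep_record <- function(x, ...) {
  cat(sprintf(
    "<sweep_record> %s, %.0f ms, %.2f in/s, %d events, noise %.1f%%\n",
    x$direction, x$duration_ms, x$speed_in_s, nrow(x$events),
    100 * x$noise_level))
  invisible(x)
}

## 0-based row-major index inside one 9x8 channel, plus the channel block.
grid_index <- function(x, y, direction) {
  chan <- match(direction, DIRECTIONS) - 1L
  chan * (GRID_NCOL * GRID_NROW) + y * GRID_NCOL + x
}

#' Fast (A-beta) spike encoding of a sweep
#'
#' One spike per touch event, delivered to the event's `(x, y)` position in
#' the event's direction channel with no added delay.
#'
#' @param sweep a `sweep_record`
#' @return spike-log data.frame with columns `time_ms`, `group`
#'   (`"TH:S1:S2"`), `neuron_index` (0-based, row-major within the
#'   channel-stacked layout)
#' @export
events_to_fast_spikes <- function(sweep) {
  ev <- sweep$events
  if (nrow(ev) == 0) {
    return(data.frame(time_ms = integer(), group = character(),
                      neuron_index = integer()))
  }
  if (any(ev$x < 0 | ev$x >= GRID_NCOL | ev$y < 0 | ev$y >= GRID_NROW)) {
    stop("touch event outside the 9x8 grid")
  }
  out <- data.frame(time_ms = as.integer(round(ev$t)),
                    group = "TH:S1:S2",
                    neuron_index = grid_index(ev$x, ev$y, ev$direction))
  out[order(out$time_ms, out$neuron_index), , drop = FALSE]
}

#' Slow (C-fiber) spike encoding of a sweep
#'
#' Each touch event opens a tonic Poisson spike train on its thalamic
#' direction-channel neuron, starting 700 ms after the event to model the
#' slower C-fiber conduction.
#'
#' @param sweep a `sweep_record`
#' @param tonic_rate_hz Poisson rate of the per-event train (default 40)
#' @param tonic_duration_ms train length per event (default 300)
#' @param conduction_delay_ms C-fiber delay (default 700)
#' @return spike-log data.frame with columns `time_ms`, `group` (`"TH"`),
#'   `neuron_index`
#' @export
events_to_slow_spikes <- function(sweep, tonic_rate_hz = 40,
                                  tonic_duration_ms = 300,
                                  conduction_delay_ms = 700) {
  stopifnot(tonic_rate_hz > 0)
  ev <- sweep$events
  if (nrow(ev) == 0) {
    return(data.frame(time_ms = integer(), group = character(),
                      neuron_index = integer()))
  }
  p <- tonic_rate_hz / 1000
  times <- integer(0); idx <- integer(0)
  ## tonic firing is refractory, not additive: the first touch of a
  ## trackball opens one tonic window on its neuron; repeated events inside
  ## the window do not extend it (the C-fiber response adapts), and events
  ## after the window reopen it.  Drive therefore scales with the touched
  ## area rather than with the raw event count.
  nid <- grid_index(ev$x, ev$y, ev$direction)
  for (i in unique(nid)) {
    tt <- sort(ev$t[nid == i]) + conduction_delay_ms
    open_t <- tt[1]
    starts <- open_t
    for (t0 in tt[-1]) {
      if (t0 > open_t + tonic_duration_ms) {
        open_t <- t0
        starts <- c(starts, open_t)
      }
    }
    for (t0 in starts) {
      k <- stats::rpois(1, p * tonic_duration_ms)
      if (k == 0) next
      ts <- as.integer(round(t0 + stats::runif(k, 0, tonic_duration_ms)))
      times <- c(times, ts)
      idx <- c(idx, rep(i, k))
    }
  }
  out <- data.frame(time_ms = times, group = "TH", neuron_index = idx)
  out[order(out$time_ms, out$neuron_index), , drop = FALSE]
}
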