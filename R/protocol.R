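## Experiment protocols: traveling-wave development and probing,
## conditioning trials (CS color -> US sweep), extinction, and the
## excitation/inhibition balance calibration onto the dopaminergic group.

#' First time a sliding-window spike-count threshold is exceeded
#'
#' Scans 50-ms (by default) windows stepped at 1 ms and returns the time
#' at which the count first exceeds `threshold` (strictly), or `NA`.
#'
#' @param times sorted spike times (ms)
#' @param threshold count that must be exceeded
#' @param window_ms window length
#' @return time of the spike that completes the first suprathreshold
#'   window, or `NA_real_`
#' @export
first_threshold_crossing <- function(times, threshold, window_ms = 50) {
  n <- length(times)
  if (n <= threshold) return(NA_real_)
  times <- sort(times)
  ## count in some window > threshold  <=>  threshold+1 consecutive spikes
  ## span less than window_ms
  span <- times[(threshold + 1):n] - times[1:(n - threshold)]
  hit <- which(span < window_ms)
  if (!length(hit)) return(NA_real_)
  times[hit[1] + threshold]
}

left_edge_volley <- function(network, channel, t, n_cols) {
  g <- network$groups[[paste0("PFC:", channel)]]
  idx <- which(g$positions[, "x"] < n_cols) - 1L
  data.frame(time_ms = t, group = g$name, neuron_index = idx)
}

#' Develop traveling waves in the PFC sheet(s)
#'
#' Runs the development protocol: with E-STDP and I-STDP enabled, a volley
#' is delivered to the leftmost columns of every PFC channel every
#' `interval_s` seconds for `total_s` seconds of simulated time.  Lateral
#' weights are updated in place; callers freeze them simply by running
#' subsequent simulations with `estdp_on = FALSE` (the protocol functions
#' do).
#'
#' @param network an `snn_network` containing PFC channels
#' @param total_s development time (s)
#' @param interval_s stimulation interval (s)
#' @param seed engine seed
#' @param noise_hz background rate during development (Hz per neuron);
#'   kept near zero so that only stimulus-launched waves shape the lateral
#'   weights
#' @return the network with developed lateral weights (attribute
#'   `pfc_developed` set)
#' @export
develop_pfc <- function(network,
                        total_s = network$config$protocol$develop_s,
                        interval_s = network$config$protocol$develop_interval_s,
                        seed = 1,
                        noise_hz = network$config$protocol$develop_noise_hz) {
  channels <- sub("^PFC:", "", grep("^PFC:", names(network$groups),
                                    value = TRUE))
  probe_rate <- list()
  for (cc in channels) {
    g <- paste0("PFC:", cc)
    probe_rate[[g]] <- network$groups[[g]]$bg_rate
    network$groups[[g]]$bg_rate <- noise_hz
  }
  if (!length(channels)) stop("network has no PFC channels")
  stim_t <- seq(0, total_s * 1000 - 1, by = interval_s * 1000)
  inputs <- do.call(rbind, lapply(channels, function(cc) {
    do.call(rbind, lapply(stim_t, function(t) {
      left_edge_volley(network, cc, t,
                       network$config$protocol$probe_stim_cols)
    }))
  }))
  res <- simulate_network(network, inputs, total_s * 1000, seed = seed,
                          estdp_on = TRUE, dastdp_on = FALSE)
  net <- res$network
  for (g in names(probe_rate)) net$groups[[g]]$bg_rate <- probe_rate[[g]]
  attr(net, "pfc_developed") <- TRUE
  net
}

#' Copy developed PFC lateral weights between networks
#'
#' PFC channels share the same realized wiring when built from the same
#' configuration and wiring seed, so lateral weights developed on a
#' standalone sheet can be installed into every channel of a full network.
#'
#' @param network target network
#' @param developed a developed standalone sheet from [build_pfc_sheet()] +
#'   [develop_pfc()]
#' @return the target network with developed lateral weights
#' @export
apply_developed_pfc <- function(network, developed) {
  src <- developed$projections
  for (tag in c("pfc_ee", "pfc_ei", "pfc_ie")) {
    s <- src[[grep(paste0("^", tag, ":"), names(src))[1]]]
    for (nm in grep(paste0("^", tag, ":"), names(network$projections),
                    value = TRUE)) {
      if (length(network$projections[[nm]]$w) != length(s$w)) {
        stop("wiring mismatch between developed sheet and target network")
      }
      network$projections[[nm]]$w <- s$w
    }
  }
  attr(network, "pfc_developed") <- TRUE
  network
}

#' Run wave probe trials on a developed sheet
#'
#' Each probe delivers a left-edge volley at t = 0 and records the
#' excitatory sheet for `trial_ms`; outcomes are scored with
#' [wave_outcome()].
#'
#' @param network a developed `snn_network` (standalone sheet or full)
#' @param n_trials number of probe trials
#' @param seed base engine seed (each trial uses `seed + trial`)
#' @param channel PFC channel name (default first)
#' @param noise_rate_hz optional override of the sheet background rate
#' @param trial_ms probe duration
#' @return data.frame with one row per trial: `trial`, `ok`, `ghosts`,
#'   `latency_ms`
#' @export
run_wave_probes <- function(network, n_trials, seed = 1, channel = NULL,
                            noise_rate_hz = NULL,
                            trial_ms = network$config$protocol$probe_trial_ms) {
  if (is.null(channel)) {
    channel <- sub("^PFC:", "", grep("^PFC:", names(network$groups),
                                     value = TRUE)[1])
  }
  gname <- paste0("PFC:", channel)
  if (!is.null(noise_rate_hz)) {
    network$groups[[gname]]$bg_rate <- noise_rate_hz
  }
  width <- network$groups[[gname]]$width
  mcfg <- network$config$metrics
  edge <- mcfg$wave_edge_cols[1]:mcfg$wave_edge_cols[2]
  out <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    inp <- left_edge_volley(network, channel, 0,
                            network$config$protocol$probe_stim_cols)
    res <- simulate_network(network, inp, trial_ms, seed = seed + k,
                            record = gname)
    sp <- res$spikes[res$spikes$group == gname, ]
    wo <- wave_outcome(sp$time_ms, sp$neuron_index %% width,
                       expected_window = mcfg$wave_window,
                       edge_cols = edge, trial_ms = trial_ms,
                       ghost_min_spikes = mcfg$ghost_min_spikes)
    out[[k]] <- data.frame(trial = k, ok = wo$ok, ghosts = wo$ghosts,
                           latency_ms = wo$latency_ms)
  }
  do.call(rbind, out)
}

## ---------------------------------------------------------------------
## conditioning trials

cs_inputs <- function(network, channel, seed_offset = 0) {
  cfg <- network$config
  p <- cfg$protocol
  ci <- match(channel, cfg$channels)
  if (is.na(ci)) stop("unknown CS channel: ", channel)
  nag <- cfg$groups$ag$n_per_channel
  ag_idx <- (ci - 1L) * nag + 0:(nag - 1L)
  packet_t <- seq(p$cs_onset_ms,
                  p$cs_onset_ms + p$ag_packet_ms - 1,
                  by = max(1, round(1000 / p$ag_packet_hz)))
  ag <- data.frame(time_ms = rep(packet_t, each = nag),
                   group = "AG",
                   neuron_index = rep(ag_idx, length(packet_t)))
  ## sustained experience drive while the color is displayed
  nexp <- cfg$groups$exp$n_per_channel
  exp_idx <- (ci - 1L) * nexp + 0:(nexp - 1L)
  lam <- p$exp_drive_hz / 1000
  drv <- lapply(exp_idx, function(i) {
    k <- stats::rpois(1, lam * p$exp_drive_ms)
    if (k == 0) return(NULL)
    data.frame(time_ms = as.integer(p$cs_onset_ms +
                 sort(stats::runif(k, 0, p$exp_drive_ms))),
               group = "EXP", neuron_index = i)
  })
  rbind(ag, do.call(rbind, drv))
}

us_inputs <- function(network, sweep) {
  cfg <- network$config
  p <- cfg$protocol
  win0 <- p$cs_onset_ms
  win1 <- p$cs_onset_ms + p$us_window_ms
  ## place the sweep uniformly inside the window (trial-by-trial CS-US
  ## interval jitter); too-long sweeps start at the window and lose their
  ## tail
  slack <- max(0, (win1 - win0) - sweep$duration_ms)
  onset <- win0 + stats::runif(1, 0, slack)
  keep <- sweep$events$t + onset <= win1
  dropped <- sum(!keep)
  sweep$events <- sweep$events[keep, , drop = FALSE]
  fast <- events_to_fast_spikes(sweep)
  slow <- events_to_slow_spikes(sweep,
                                cfg$tactile$tonic_rate_hz,
                                cfg$tactile$tonic_duration_ms,
                                cfg$tactile$conduction_delay_ms)
  for (df in list(fast, slow)) stopifnot(all(df$time_ms >= 0))
  fast$time_ms <- as.integer(round(fast$time_ms + onset))
  slow$time_ms <- as.integer(round(slow$time_ms + onset))
  list(spikes = rbind(fast, slow), onset = onset, dropped = dropped)
}

#' Run one 6-s conditioning trial
#'
#' Delivers the CS packet to the AG channel at the configured onset
#' (1100 ms), optionally encodes and delivers a US sweep inside the 2-s US
#' window, simulates the full trial with DA-STDP active, and extracts
#' behaviour events and dopamine statistics.
#'
#' @param network a calibrated, developed `snn_network`
#' @param cs_channel color channel name
#' @param us_sweep `NULL` (CS-only) or a `sweep_record`
#' @param seed engine seed for this trial
#' @param dastdp_on enable dopamine-modulated plasticity (default TRUE)
#' @param keep_spikes include the recorded spike log in the result
#' @return a `trial_record` list: `behaviors` (data.frame `kind`, `time_ms`),
#'   `da_cs`, `da_us` (spike counts in the response windows), `dip_ms`,
#'   `us_onset`, `dropped_events`, `counts`, `network`
#' @export
run_trial <- function(network, cs_channel, us_sweep = NULL, seed = 1,
                      dastdp_on = TRUE, keep_spikes = FALSE) {
  cfg <- network$config
  p <- cfg$protocol
  inputs <- cs_inputs(network, cs_channel)
  us <- NULL
  if (!is.null(us_sweep)) {
    us <- us_inputs(network, us_sweep)
    inputs <- rbind(inputs, us$spikes)
  }
  res <- simulate_network(network, inputs, p$trial_ms, seed = seed,
                          record = c("DA", "INT", "mIC"),
                          dastdp_on = dastdp_on)
  sp <- res$spikes
  stopifnot(all(sp$time_ms <= p$trial_ms))
  da_t <- sp$time_ms[sp$group == "DA"]
  int_t <- sp$time_ms[sp$group == "INT"]
  mic_t <- sp$time_ms[sp$group == "mIC"]

  cr_t <- first_threshold_crossing(int_t, p$cr_threshold, p$cr_window_ms)
  ur_t <- first_threshold_crossing(mic_t, p$ur_threshold, p$ur_window_ms)
  dip_win <- c(p$cs_onset_ms,
               p$cs_onset_ms + p$us_window_ms + p$dip_search_pad_ms)
  dip <- detect_da_dip(da_t, dip_win)
  behaviors <- data.frame(kind = character(0), time_ms = numeric(0))
  if (!is.na(cr_t)) {
    behaviors <- rbind(behaviors, data.frame(kind = "CR", time_ms = cr_t))
  }
  if (!is.na(ur_t)) {
    behaviors <- rbind(behaviors, data.frame(kind = "UR", time_ms = ur_t))
  }
  if (dip > p$low_tone_dip_ms) {
    behaviors <- rbind(behaviors,
                       data.frame(kind = "low_tone",
                                  time_ms = dip_win[1] + dip))
  }
  cs_win <- p$cs_onset_ms + p$da_latency_ms + c(0, p$da_response_ms)
  da_cs <- sum(da_t >= cs_win[1] & da_t < cs_win[2])
  da_us <- NA_real_
  if (!is.null(us)) {
    ## the reward-related dopamine response follows the slow (C-fiber)
    ## pathway, so the US window starts one conduction delay after the
    ## sweep onset and spans the tonic integration period
    us_win <- us$onset + cfg$tactile$conduction_delay_ms +
      c(0, p$da_us_response_ms)
    da_us <- sum(da_t >= us_win[1] & da_t < us_win[2])
  }
  structure(list(behaviors = behaviors, da_cs = da_cs, da_us = da_us,
                 dip_ms = dip, us_onset = if (is.null(us)) NA else us$onset,
                 dropped_events = if (is.null(us)) 0L else us$dropped,
                 counts = res$counts, network = res$network,
                 spikes = if (keep_spikes) sp else NULL),
            class = "trial_record")
}

session_row <- function(trial, channel, rewarded, tr) {
  data.frame(trial = trial, channel = channel, rewarded = rewarded,
             cr = "CR" %in% tr$behaviors$kind,
             ur = "UR" %in% tr$behaviors$kind,
             low_tone = "low_tone" %in% tr$behaviors$kind,
             da_cs = tr$da_cs, da_us = tr$da_us, dip_ms = tr$dip_ms,
             us_onset = tr$us_onset)
}

exp_int_channel_means <- function(network) {
  pr <- network$projections$exp_int
  nexp <- network$config$groups$exp$n_per_channel
  ch <- network$config$channels
  chan <- pr$pre_idx %/% nexp + 1L
  vapply(seq_along(ch), function(i) mean(pr$w[chan == i]), 0)
}

#' Run a conditioning session
#'
#' Cycles through the colors of the pairing policy; rewarded colors get a
#' US sweep in their paired direction, unrewarded colors a CS-only trial.
#' DA-STDP is active throughout; E/I-STDP stays frozen.
#'
#' @param network calibrated, developed network
#' @param policy named list mapping color -> sweep direction, or `NA` for
#'   no US (e.g. `list(yellow = "down", blue = "right")`)
#' @param n_trials total number of trials
#' @param seed master seed (sweep draws and engine seeds derive from it)
#' @param snapshot_every record weight snapshots every this many trials
#' @return list with `session` (one row per trial), `network` (final
#'   weights), `snapshots` (per-snapshot EXP->INT channel means and
#'   PFC->STR weight maps)
#' @export
run_conditioning_session <- function(network, policy, n_trials, seed = 1,
                                     snapshot_every = 40) {
  colors <- names(policy)
  rows <- vector("list", n_trials)
  snaps <- list()
  set.seed(substream_seed(seed, "conditioning"))
  for (k in seq_len(n_trials)) {
    cc <- colors[(k - 1) %% length(colors) + 1]
    dir <- policy[[cc]]
    sweep <- if (is.null(dir) || is.na(dir)) NULL else sample_sweep(dir)
    tr <- run_trial(network, cc, sweep,
                    seed = substream_seed(seed, paste0("trial", k)))
    network <- tr$network
    rows[[k]] <- session_row(k, cc, !is.null(sweep), tr)
    if (k %% snapshot_every == 0) {
      snaps[[length(snaps) + 1]] <- list(
        trial = k, exp_int = exp_int_channel_means(network))
    }
  }
  list(session = do.call(rbind, rows), network = network,
       snapshots = snaps)
}

#' Run an extinction session (CS-only trials)
#'
#' @param network a previously conditioned network
#' @param cs_channel the conditioned color
#' @param n_trials number of CS-only trials
#' @param seed master seed
#' @return list with `session` (per-trial CR/dip/low-tone and the mean
#'   EXP->INT weight of the CS channel) and `network`
#' @export
run_extinction_session <- function(network, cs_channel, n_trials,
                                   seed = 1) {
  rows <- vector("list", n_trials)
  ci <- match(cs_channel, network$config$channels)
  for (k in seq_len(n_trials)) {
    tr <- run_trial(network, cs_channel, NULL,
                    seed = substream_seed(seed, paste0("trial", k)))
    network <- tr$network
    r <- session_row(k, cs_channel, FALSE, tr)
    r$w_exp_int <- exp_int_channel_means(network)[ci]
    rows[[k]] <- r
  }
  list(session = do.call(rbind, rows), network = network)
}

## ---------------------------------------------------------------------
## balance calibration

scale_projection <- function(network, name, scale) {
  network$projections[[name]]$w <- network$projections[[name]]$w * scale
  network
}

#' Calibrate the excitation/inhibition balance onto the DA group
#'
#' With plasticity frozen, searches multiplicative scale factors for the
#' STR->DA (inhibitory) and INT->DA (excitatory) weights so that (i) the
#' baseline DA population rate stays in the configured band, (ii) a
#' standard INT volley evokes a detectable DA burst, and (iii) a standard
#' STR volley silences DA for at least the dip threshold.  A pIC volley is
#' additionally verified to evoke a burst through mIC.
#'
#' @param network an `snn_network`
#' @param seed engine seed
#' @param baseline_band acceptable baseline DA rate per neuron (Hz)
#' @param probe_ms probe simulation length
#' @return list with `str_scale`, `int_scale`, `report` (the search
#'   trace), and `network` with scales applied
#' @export
calibrate_balance <- function(network, seed = 1,
                              baseline_band = c(2, 9), probe_ms = 3000) {
  nda <- network$config$groups$da$n
  dip_needed <- network$config$protocol$low_tone_dip_ms
  report <- list()

  da_rate <- function(net) {
    res <- simulate_network(net, NULL, probe_ms, seed = seed,
                            record = "DA")
    sum(res$spikes$group == "DA") / nda / (probe_ms / 1000)
  }
  base_rate <- da_rate(network)
  report$baseline_hz <- base_rate
  if (base_rate < baseline_band[1] || base_rate > baseline_band[2]) {
    stop("calibration failure: baseline DA rate ", round(base_rate, 2),
         " Hz outside [", baseline_band[1], ", ", baseline_band[2], "]")
  }

  volley <- function(group, n_neurons, t0, dur, rate) {
    nn <- network$groups[[group]]$n
    idx <- sample.int(nn, min(n_neurons, nn)) - 1L
    do.call(rbind, lapply(idx, function(i) {
      k <- stats::rpois(1, rate * dur / 1000)
      if (k == 0) return(NULL)
      data.frame(time_ms = as.integer(t0 + sort(stats::runif(k, 0, dur))),
                 group = group, neuron_index = i)
    }))
  }

  dip_for <- function(scale) {
    net <- scale_projection(network, "str_da", scale)
    set.seed(substream_seed(seed, "calib_str"))
    inp <- volley("STR", 200, 1000, 300, 100)
    res <- simulate_network(net, inp, probe_ms, seed = seed, record = "DA")
    detect_da_dip(res$spikes$time_ms[res$spikes$group == "DA"],
                  c(1000, probe_ms))
  }
  burst_for <- function(scale) {
    net <- scale_projection(network, "int_da", scale)
    set.seed(substream_seed(seed, "calib_int"))
    inp <- volley("INT", 100, 1000, 100, 200)
    res <- simulate_network(net, inp, probe_ms, seed = seed, record = "DA")
    br <- detect_da_bursts(res$spikes$time_ms[res$spikes$group == "DA"],
                           c(500, probe_ms), baseline_window = c(0, 500))
    nrow(br$bursts)
  }

  search_up <- function(f, ok, scales) {
    trace <- data.frame(scale = numeric(0), value = numeric(0))
    for (s in scales) {
      v <- f(s)
      trace <- rbind(trace, data.frame(scale = s, value = v))
      if (ok(v)) return(list(scale = s, trace = trace))
    }
    list(scale = NA_real_, trace = trace)
  }
  grid <- c(1, 1.5, 2, 3, 4, 6, 8)
  str_res <- search_up(dip_for, function(v) v >= dip_needed, grid)
  int_res <- search_up(burst_for, function(v) v >= 1, grid)
  report$str_trace <- str_res$trace
  report$int_trace <- int_res$trace
  if (is.na(str_res$scale) || is.na(int_res$scale)) {
    stop("calibration failure: no feasible scale in [",
         min(grid), ", ", max(grid), "]; see report traces")
  }
  network <- scale_projection(network, "str_da", str_res$scale)
  network <- scale_projection(network, "int_da", int_res$scale)

  ## verification: a pIC volley evokes a burst through mIC
  set.seed(substream_seed(seed, "calib_pic"))
  inp <- volley("pIC", 150, 1000, 150, 150)
  res <- simulate_network(network, inp, probe_ms, seed = seed,
                          record = "DA")
  br <- detect_da_bursts(res$spikes$time_ms[res$spikes$group == "DA"],
                         c(500, probe_ms), baseline_window = c(0, 500))
  report$pic_volley_bursts <- nrow(br$bursts)

  list(str_scale = str_res$scale, int_scale = int_res$scale,
       report = report, network = network)
}

## ---------------------------------------------------------------------
## burst-probability sweep over TH->pIC weights

#' Run one tactile sweep through the incremental-pathway subnetwork
#'
#' @param network an incremental subnetwork from
#'   [build_incremental_network()]
#' @param sweep a `sweep_record`
#' @param seed engine seed
#' @param onset_ms time at which the sweep starts (default 200)
#' @return the `burst_report` for the trial
#' @export
run_tactile_trial <- function(network, sweep, seed = 1, onset_ms = 200) {
  cfg <- network$config
  fast <- events_to_fast_spikes(sweep)
  slow <- events_to_slow_spikes(sweep, cfg$tactile$tonic_rate_hz,
                                cfg$tactile$tonic_duration_ms,
                                cfg$tactile$conduction_delay_ms)
  inputs <- rbind(fast, slow)
  inputs$time_ms <- inputs$time_ms + onset_ms
  dur <- onset_ms + ceiling(sweep$duration_ms) +
    cfg$tactile$conduction_delay_ms + cfg$tactile$tonic_duration_ms + 500
  res <- simulate_network(network, inputs, dur, seed = seed,
                          record = "DA")
  da_t <- res$spikes$time_ms[res$spikes$group == "DA"]
  nda <- cfg$groups$da$n
  ## Poisson-based baseline from the configured spontaneous rate; the
  ## count floor is set so that a pure-Poisson baseline trial has < 1%
  ## probability of any false burst across all sliding bins
  mu <- cfg$groups$da$bg_rate * nda *
    cfg$metrics$burst_bin_ms / 1000
  nbins <- (dur - onset_ms) / cfg$metrics$burst_step_ms
  ## a population burst must also engage a substantial fraction of the
  ## dopaminergic cells within one bin, not just exceed Poisson noise
  floor_n <- max(stats::qpois(1 - 0.01 / nbins, mu) + 1,
                 cfg$metrics$burst_min_frac * nda)
  detect_da_bursts(da_t, c(onset_ms, dur),
                   baseline_mean = mu, baseline_sd = sqrt(mu),
                   bin_ms = cfg$metrics$burst_bin_ms,
                   bin_step_ms = cfg$metrics$burst_step_ms,
                   merge_gap_ms = cfg$metrics$burst_merge_ms,
                   min_count = max(cfg$metrics$burst_min_count, floor_n))
}

#' Burst probabilities over TH->pIC weights and sweep directions
#'
#' For each weight in `weights`, all four slow-pathway channel weights are
#' set to that value; `n_per_cell` synthetic sweeps are run per direction
#' through the incremental subnetwork, and the fraction classified as a
#' single or multiple dopamine burst is tabulated.
#'
#' @param config configuration list
#' @param weights numeric vector of TH->pIC weights
#' @param directions sweep directions to test
#' @param n_per_cell sweeps per (weight, direction) cell
#' @param seed master seed
#' @return data.frame with columns `weight`, `direction`, `p_single`,
#'   `p_multiple`
#' @export
burst_probability_sweep <- function(config = default_config(),
                                    weights,
                                    directions = c("up", "down", "left",
                                                   "right"),
                                    n_per_cell = 50, seed = 1) {
  out <- list()
  for (w in weights) {
    set.seed(substream_seed(seed, paste0("wiring", w)))
    net <- build_incremental_network(
      config, th_pic_w = stats::setNames(as.list(rep(w, 4)),
                                         c("up", "down", "left", "right")))
    for (dd in directions) {
      set.seed(substream_seed(seed, paste0("sweep", w, dd)))
      cls <- character(n_per_cell)
      for (k in seq_len(n_per_cell)) {
        sw <- sample_sweep(dd)
        br <- run_tactile_trial(net, sw,
                                seed = substream_seed(seed,
                                                      paste0("cell", k)))
        cls[k] <- br$classification
      }
      out[[length(out) + 1]] <- data.frame(
        weight = w, direction = dd,
        p_single = mean(cls == "single"),
        p_multiple = mean(cls == "multiple"))
    }
  }
  do.call(rbind, out)
}
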