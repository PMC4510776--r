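## Configuration: defaults, YAML loading with schema validation, saving.

#' Default configuration
#'
#' The complete parameter set of the simulator: group sizes and background
#' rates, projection radii/weights/delays, plasticity constants, protocol
#' timing and metric windows.  Values not fixed by the circuit description
#' (most initial weights and unreported population sizes) are package
#' defaults chosen for stable dynamics and are all overridable from a YAML
#' file via [load_config()].
#'
#' @return nested named list
#' @export
default_config <- function() {
  list(
    schema = 1L,
    rng_seed = 1L,
    channels = c("red", "green", "blue", "yellow"),
    groups = list(
      ag = list(n_per_channel = 16L),
      pfc = list(width = 512L, height = 4L, inh_n = 512L,
                 bg_rate = 0.01, bg_weight = 0.15),
      str = list(n = 512L, bg_rate = 0.3, bg_weight = 0.13),
      exp = list(n_per_channel = 16L, bg_rate = 0.5, bg_weight = 0.13),
      int = list(n = 256L, bg_rate = 1.0, bg_weight = 0.13),
      pic = list(inh_frac = 0.25, bg_rate = 0.1, bg_weight = 0.13),
      mic = list(n = 64L, bg_rate = 0.1, bg_weight = 0.13),
      da = list(n = 100L, bg_rate = 3.0, bg_weight = 0.13)
    ),
    projections = list(
      ag_pfc = list(radius = 2, w = 0.5, delay = 200L, ampa_frac = 1.0),
      pfc_ee = list(radius = 3, w_init = 0.052, w_min = 0.052, w_max = 0.068,
                    delay_lo = 7.1, delay_hi = 9.5, ampa_frac = 1.0),
      pfc_ei = list(radius = 3, w = 0.03, delay = 1L, ampa_frac = 1.0),
      pfc_ie = list(radius = 5, w_init = 0.04, w_min = 0.035, w_max = 0.045,
                    delay = 1L, gabaa_frac = 0.8),
      pfc_str = list(radius = 2, w_init = 0.002, w_min = 0, w_max = 0.025,
                     delay = 1L, ampa_frac = 0.8),
      str_da = list(p = 0.25, w = 0.12, delay = 1L, gabaa_frac = 0.9),
      ag_exp = list(p = 1.0, w = 0.05, delay = 1L, ampa_frac = 1.0),
      exp_int = list(p = 1.0, w_init = 0.001, w_min = 0, w_max = 0.015,
                     delay = 1L, ampa_frac = 0.5),
      int_da = list(p = 0.25, w = 0.03, delay = 1L, ampa_frac = 0.9),
      ths_pic = list(radius = 1.5, w = 0.03, delay = 1L, ampa_frac = 1.0),
      th_pic = list(w = list(up = 0.04, down = 0.04, left = 0.04,
                             right = 0.04),
                    delay = 1L, ampa_frac = 0.9, p = 0.3),
      th_pici = list(w_scale = 0.4),
      ths_pici = list(w = 0.3, ampa_frac = 1.0),
      pic_ee = list(radius = 2, w = 0.05, delay = 2L, ampa_frac = 1.0),
      pic_ei = list(radius = 2, w = 0.10, delay = 1L, ampa_frac = 1.0),
      pic_ie = list(radius = 4, w = 0.20, delay = 1L, gabaa_frac = 1.0),
      pic_mic = list(p = 0.3, w = 0.048, delay = 1L, ampa_frac = 0.1),
      mic_pici = list(p = 0.5, w = 0.40, delay = 1L, ampa_frac = 0.3),
      mic_da = list(p = 0.3, w = 0.30, w_subnet = 0.19, delay = 1L,
                    ampa_frac = 0.5)
    ),
    plasticity = list(
      estdp = list(A_plus = 0.1, A_minus = 0.07, tau_plus = 20,
                   tau_minus = 40, tau_c = 1000),
      istdp = list(B_plus = 0.1, B_minus = 0.06, lambda_win = 4,
                   gamma_win = 20),
      da_pool = list(tau_d = 50, da_syn = 0.04, baseline = 1.0,
                     peak = 20.0),
      psf_int = TRUE
    ),
    tactile = list(tonic_rate_hz = 40, tonic_duration_ms = 300,
                   conduction_delay_ms = 700),
    protocol = list(
      trial_ms = 6000L, cs_onset_ms = 1100L, us_window_ms = 2000L,
      ag_packet_ms = 20L, ag_packet_hz = 100,
      exp_drive_hz = 33, exp_drive_ms = 2000L,
      cr_threshold = 50L, cr_window_ms = 50L,
      ur_threshold = 30L, ur_window_ms = 50L,
      low_tone_dip_ms = 400,
      da_latency_ms = 50L, da_response_ms = 200L, da_us_response_ms = 700L,
      dip_search_pad_ms = 500L,
      develop_s = 2000L, develop_interval_s = 4L, develop_noise_hz = 0.001,
      probe_trial_ms = 2500L, probe_stim_cols = 4L
    ),
    metrics = list(
      burst_bin_ms = 50, burst_step_ms = 10, burst_merge_ms = 200,
      burst_min_count = 5, burst_min_frac = 2.5,
      wave_window = c(1950, 2050), wave_edge_cols = c(508L, 511L),
      ghost_min_spikes = 2L
    )
  )
}

merge_config <- function(defaults, user, path = "") {
  report <- character(0)
  for (key in names(defaults)) {
    kp <- if (path == "") key else paste0(path, ".", key)
    if (is.null(user[[key]])) {
      report <- c(report, kp)
    } else if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      sub <- merge_config(defaults[[key]], user[[key]], kp)
      defaults[[key]] <- sub$config
      report <- c(report, sub$defaulted)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    kp <- if (path == "") extra else paste0(path, ".", extra)
    stop("unknown configuration key(s): ", paste(kp, collapse = ", "))
  }
  list(config = defaults, defaulted = report)
}

#' Load and validate a configuration file
#'
#' Reads a YAML document, fills unspecified keys from [default_config()],
#' and rejects unknown keys (reporting the full key path).  The returned
#' object carries the list of defaulted key paths in the
#' `"defaulted_keys"` attribute.
#'
#' @param path YAML file path
#' @return validated configuration list
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  m <- merge_config(default_config(), user)
  cfg <- m$config
  cfg$channels <- as.character(cfg$channels)
  attr(cfg, "defaulted_keys") <- m$defaulted
  cfg
}

#' Save a configuration to YAML
#'
#' A saved-then-reloaded configuration is identical to the original
#' (`load_config(save_config(cfg)) == cfg`).
#'
#' @param config configuration list
#' @param path output file
#' @return `path`, invisibly
#' @export
save_config <- function(config, path) {
  attr(config, "defaulted_keys") <- NULL
  yaml::write_yaml(config, path)
  invisible(path)
}
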