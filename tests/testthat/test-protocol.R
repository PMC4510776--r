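test_that("an undeveloped sheet fails to carry the wave to the right edge", {
  cfg <- default_config()
  set.seed(6)
  net <- build_pfc_sheet(cfg)
  pro <- run_wave_probes(net, 2, seed = 3, noise_rate_hz = 0)
  expect_true(all(!pro$ok))
})

test_that("tactile input is only generated inside the US window", {
  cfg <- default_config()
  set.seed(8)
  net <- build_incremental_network(cfg)
  net$config <- cfg
  set.seed(9)
  sw <- sample_sweep("down")
  sw$duration_ms <- 3000   # longer than the 2-s window: tail must drop
  sw$events$t <- sw$events$t * 3
  us <- dawave:::us_inputs(net, sw)
  p <- cfg$protocol
  win1 <- p$cs_onset_ms + p$us_window_ms
  fast <- us$spikes[us$spikes$group == "TH:S1:S2", ]
  expect_true(all(fast$time_ms <= win1 + 1))
  expect_gt(us$dropped, 0)
  expect_gte(us$onset, p$cs_onset_ms)
})

test_that("trial records stay inside the 6-s trial clock", {
  cfg <- default_config()
  cfg$channels <- "yellow"
  set.seed(10)
  net <- build_network(cfg)
  set.seed(11)
  tr <- run_trial(net, "yellow", sample_sweep("down"), seed = 2,
                  keep_spikes = TRUE, dastdp_on = FALSE)
  expect_lte(max(tr$spikes$time_ms), cfg$protocol$trial_ms)
  expect_true(all(c("behaviors", "da_cs", "da_us", "dip_ms")
                  %in% names(unclass(tr))))
})

test_that("a CS-only trial on a naive network produces no unconditioned response", {
  cfg <- default_config()
  cfg$channels <- "yellow"
  set.seed(10)
  net <- build_network(cfg)
  tr <- run_trial(net, "yellow", NULL, seed = 4, dastdp_on = FALSE)
  expect_false("UR" %in% tr$behaviors$kind)
  expect_true(is.na(tr$da_us))
})

test_that("behaviour thresholds are strict inequalities", {
  ## 51 spikes inside 50 ms crosses the >50 rule; 50 does not
  t51 <- seq(0, 49, length.out = 51)
  expect_false(is.na(first_threshold_crossing(t51, 50, 50)))
  expect_true(is.na(first_threshold_crossing(t51[-1], 50, 50)))
  ## dip boundary: exactly 400 ms is not a low tone, 401 is
  da1 <- c(1000, 1400)   # a 400-ms gap
  expect_false(detect_da_dip(da1, c(1000, 1400)) >
                 default_config()$protocol$low_tone_dip_ms)
  da2 <- c(1000, 1401)
  expect_true(detect_da_dip(da2, c(1000, 1401)) >
                default_config()$protocol$low_tone_dip_ms)
})

test_that("empty sessions produce empty records", {
  cfg <- default_config()
  cfg$channels <- "yellow"
  set.seed(10)
  net <- build_network(cfg)
  out <- run_conditioning_session(net, list(yellow = "down"), 0, seed = 1)
  expect_null(out$session)
})
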