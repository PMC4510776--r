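test_that("sweep sample moments match the measured statistics", {
  set.seed(101)
  n <- 500
  for (cls in c("vertical", "horizontal")) {
    dirs <- if (cls == "vertical") c("up", "down") else c("left", "right")
    sweeps <- replicate(n, sample_sweep(sample(dirs, 1)),
                        simplify = FALSE)
    st <- SWEEP_STATS[[cls]]
    dur <- sapply(sweeps, `[[`, "duration_ms")
    spd <- sapply(sweeps, `[[`, "speed_in_s")
    nev <- sapply(sweeps, function(s) nrow(s$events))
    noi <- 100 * sapply(sweeps, `[[`, "noise_level")
    expect_lt(abs(mean(dur) - st$duration_ms[1]),
              3 * st$duration_ms[2] / sqrt(n))
    expect_lt(abs(mean(spd) - st$speed_in_s[1]),
              3 * st$speed_in_s[2] / sqrt(n))
    expect_lt(abs(mean(nev) - st$n_events[1]),
              3 * st$n_events[2] / sqrt(n))
    ## realized noise is a ratio of counts; allow its own spread
    expect_lt(abs(mean(noi) - st$noise_pct[1]),
              4 * st$noise_pct[2] / sqrt(n) + 0.5)
  }
})

test_that("zero noise yields only intended-direction events on the swept path", {
  set.seed(5)
  for (dd in c("up", "down", "left", "right")) {
    sw <- sample_sweep(dd, noise_override = 0)
    ev <- sw$events
    expect_true(all(ev$direction == dd))
    expect_true(all(ev$x >= 0 & ev$x <= 8 & ev$y >= 0 & ev$y <= 7))
    ## position along the movement axis is monotone in time, the cross
    ## axis stays inside the footprint band
    if (dd %in% c("up", "down")) {
      axis <- if (dd == "down") ev$y else -ev$y
      expect_true(all(diff(axis) >= 0))
      expect_lte(diff(range(ev$x)) + 1, sw$footprint)
    } else {
      axis <- if (dd == "right") ev$x else -ev$x
      expect_true(all(diff(axis) >= 0))
      expect_lte(diff(range(ev$y)) + 1, sw$footprint)
    }
    expect_true(sw$footprint %in% 4:7)
  }
})

test_that("fast encoding is one spike per event at the somatotopic position", {
  set.seed(9)
  sw <- sample_sweep("down")
  sp <- events_to_fast_spikes(sw)
  expect_equal(nrow(sp), nrow(sw$events))
  expect_true(all(sp$group == "TH:S1:S2"))
  ## worked position: an event at (x=3, y=2) in the down channel
  sw2 <- sw
  sw2$events <- data.frame(x = 3L, y = 2L, direction = "down", t = 120)
  sp2 <- events_to_fast_spikes(sw2)
  expect_equal(sp2$time_ms, 120L)
  expect_equal(sp2$neuron_index, 1L * 72L + 2L * 9L + 3L)
  ## empty sweep
  sw2$events <- sw$events[0, ]
  expect_equal(nrow(events_to_fast_spikes(sw2)), 0)
  ## out-of-grid event rejected
  sw2$events <- data.frame(x = 9L, y = 0L, direction = "down", t = 0)
  expect_error(events_to_fast_spikes(sw2), "grid")
})

test_that("slow encoding is delayed by the C-fiber latency", {
  set.seed(13)
  sw <- sample_sweep("up")
  sp <- events_to_slow_spikes(sw)
  expect_true(all(sp$group == "TH"))
  expect_gte(min(sp$time_ms), 700)
  sw$events <- sw$events[0, ]
  expect_equal(nrow(events_to_slow_spikes(sw)), 0)
})

test_that("slow spike counts follow the Poisson-train expectation for isolated events", {
  ## events on distinct trackballs, spaced beyond the tonic window, so
  ## every event opens one full window
  set.seed(21)
  n_ev <- 60; rate <- 40; dur <- 300
  counts <- replicate(30, {
    sw <- structure(list(direction = "up", duration_ms = 50000,
                         events = data.frame(
                           x = rep(0:8, length.out = n_ev),
                           y = rep(0:7, each = 9)[seq_len(n_ev)],
                           direction = "up",
                           t = seq(0, by = 500, length.out = n_ev))),
                    class = "sweep_record")
    nrow(events_to_slow_spikes(sw, rate, dur))
  })
  expected <- n_ev * rate * dur / 1000
  se <- sqrt(expected / 30)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("sweeps shorter than the conduction delay leave no fast/slow overlap", {
  set.seed(33)
  sw <- sample_sweep("up")
  sw$duration_ms <- 500
  sw$events <- sw$events[sw$events$t < 500, ]
  fast <- events_to_fast_spikes(sw)
  slow <- events_to_slow_spikes(sw)
  expect_lt(max(fast$time_ms), min(slow$time_ms))
})
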