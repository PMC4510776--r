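test_that("dip detector returns the longest spike-free interval", {
  expect_equal(detect_da_dip(numeric(0), c(0, 600)), 600)
  expect_equal(detect_da_dip(seq(0, 1000, by = 10), c(100, 900)), 10)
  log <- c(seq(0, 500, by = 5), seq(950, 1500, by = 5))
  expect_equal(detect_da_dip(log, c(0, 1500)), 450)
})

test_that("dip detector agrees with a brute-force millisecond scan", {
  brute <- function(times, win) {
    ms <- win[1]:win[2]
    occ <- ms %in% round(times)
    best <- 0; run <- 0
    for (i in seq_along(ms)) {
      if (occ[i]) run <- 0 else run <- run + 1
      best <- max(best, run)
    }
    best
  }
  set.seed(8)
  for (rep in 1:200) {
    times <- sort(sample(0:2000, rpois(1, 40)))
    win <- c(0, 2000)
    got <- detect_da_dip(times, win)
    ## brute force counts empty milliseconds; the detector measures real
    ## gaps -- they agree up to the unit discretization
    expect_lt(abs(got - brute(times, win)), 1 + 1e-9)
  }
})

test_that("burst detection classifies none, single and multiple", {
  expect_equal(detect_da_bursts(numeric(0), c(0, 2000),
                                baseline_window = c(0, 500))$classification,
               "none")
  ## two volleys 500 ms apart on a quiet baseline: multiple
  volley <- function(t0) rep(t0 + 0:9, each = 10)
  log <- sort(c(volley(800), volley(1300)))
  br <- detect_da_bursts(log, c(500, 2000), baseline_mean = 2,
                         baseline_sd = 1.4)
  expect_equal(br$classification, "multiple")
  expect_equal(nrow(br$bursts), 2)
  ## volleys 100 ms apart merge into a single burst
  log <- sort(c(volley(800), volley(950)))
  br <- detect_da_bursts(log, c(500, 2000), baseline_mean = 2,
                         baseline_sd = 1.4)
  expect_equal(br$classification, "single")
})

test_that("Poisson baselines rarely produce false bursts at the calibrated floor", {
  set.seed(99)
  mu <- 15
  false_pos <- replicate(60, {
    log <- sort(runif(rpois(1, 0.3 * 3000), 0, 3000))
    nbins <- 3000 / 10
    floor_n <- qpois(1 - 0.01 / nbins, mu) + 1
    br <- detect_da_bursts(log, c(0, 3000), baseline_mean = mu,
                           baseline_sd = sqrt(mu), min_count = floor_n)
    nrow(br$bursts) > 0
  })
  expect_lt(mean(false_pos), 0.05)
})

test_that("wave outcomes follow the expected-window rule", {
  ## edge spikes only inside the window: ok, no ghosts
  times <- c(2000, 2003, 2006, 2010)
  cols <- rep(510, 4)
  wo <- wave_outcome(times, cols)
  expect_true(wo$ok)
  expect_equal(wo$ghosts, 0L)
  ## no edge spikes anywhere: fail
  wo <- wave_outcome(c(100, 500), c(10, 20))
  expect_false(wo$ok)
  ## an extra early edge episode: ok with one ghost
  times <- c(1000, 1004, 1008, 2000, 2004, 2008)
  cols <- rep(509, 6)
  wo <- wave_outcome(times, cols)
  expect_true(wo$ok)
  expect_equal(wo$ghosts, 1L)
  ## a single stray edge spike does not count as ghost activity
  wo <- wave_outcome(c(1000, 2000, 2004, 2008), rep(509, 4))
  expect_equal(wo$ghosts, 0L)
})

test_that("weight maps sum outgoing weights on the pre layout", {
  proj <- list(pre = integer(0), w = numeric(0))
  expect_equal(weight_map(proj, c(512, 4)), matrix(0, 4, 512))
  ## single synapse of weight 0.5 from the neuron at (x=290, y=2)
  proj <- list(pre = 2L * 512L + 290L, w = 0.5)
  m <- weight_map(proj, c(512, 4))
  expect_equal(m[3, 291], 0.5)
  expect_equal(sum(m), 0.5)
  ## conservation over a random projection
  set.seed(4)
  proj <- list(pre = sample(0:(512 * 4 - 1), 300, replace = TRUE),
               w = runif(300))
  expect_equal(sum(weight_map(proj, c(512, 4))), sum(proj$w))
})

test_that("sliding threshold crossings report the completing spike time", {
  expect_true(is.na(first_threshold_crossing(1:50, 50, 50)))
  t51 <- c(seq(1000, 1049, length.out = 51))
  expect_equal(first_threshold_crossing(t51, 50, 50), 1049)
  expect_true(is.na(first_threshold_crossing(seq(1000, 1100, by = 2),
                                             50, 50)))
})
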