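test_that("neuron presets match the regular- and fast-spiking parameters", {
  rs <- neuron_params("RS")
  expect_equal(unlist(rs), c(a = 0.02, b = 0.2, c_reset = -65, d_jump = 8))
  fs <- neuron_params("FS")
  expect_equal(unlist(fs), c(a = 0.1, b = 0.2, c_reset = -65, d_jump = 2))
})

test_that("suprathreshold membrane is reported as a spike and reset", {
  st <- membrane_state(v = 31, u = -10)
  out <- step_membrane(st, neuron_params("RS"), 0)
  expect_equal(out$spikes, 1L)
  expect_equal(out$state$v, -65)
  expect_equal(out$state$u, -10 + 8)
})

test_that("the resting point (-70, -14) is a fixed point at zero input", {
  st <- resting_state(1)
  for (i in 1:50) {
    out <- step_membrane(st, neuron_params("RS"), 0)
    st <- out$state
    expect_length(out$spikes, 0)
  }
  expect_equal(st$v, -70, tolerance = 1e-12)
  expect_equal(st$u, -14, tolerance = 1e-12)
})

test_that("no membrane exceeds threshold after a step and spikes match pre-reset crossings", {
  set.seed(1)
  for (rep in 1:20) {
    v <- runif(50, -80, 40)
    st <- membrane_state(v, runif(50, -20, 5))
    out <- step_membrane(st, neuron_params("RS"), runif(50, 0, 30))
    expect_true(all(out$state$v <= IZH_SPIKE_THRESHOLD))
    ## every neuron already at or above threshold on entry must spike
    expect_true(all(which(v >= 30) %in% out$spikes))
  }
})

test_that("tonic firing under sustained current has a stable inter-spike interval", {
  st <- resting_state(1)
  spikes <- numeric(0)
  for (t in 1:2000) {
    out <- step_membrane(st, neuron_params("RS"), 10)
    st <- out$state
    if (length(out$spikes)) spikes <- c(spikes, t)
  }
  expect_gt(length(spikes), 6)
  isi <- diff(spikes)[-(1:3)]
  expect_lt(sd(isi) / mean(isi), 0.05)
})

test_that("non-finite state aborts with the neuron index", {
  st <- membrane_state(c(-70, NaN), c(-14, -14))
  expect_error(step_membrane(st, neuron_params("RS"), 0),
               "divergence.*2")
})

test_that("synaptic currents vanish at zero conductance and at reversal potentials", {
  rc <- receptor_state(3)
  expect_equal(synaptic_current(rc, c(-70, 0, 30)), c(0, 0, 0))
  rc <- receptor_state(1, g_gabaa = 2)
  expect_equal(synaptic_current(rc, -70), 0)
  rc <- receptor_state(1, g_nmda = 5)
  expect_equal(synaptic_current(rc, -80), 0)
  ## GABA_A drives toward -70 from either side
  rc <- receptor_state(1, g_gabaa = 1)
  expect_lt(synaptic_current(rc, -60), 0)
  expect_gt(synaptic_current(rc, -80), 0)
})

test_that("conductances decay by the closed form for all four receptors", {
  g0 <- c(1.0, 0.5, 2.0, 0.25)
  rc <- receptor_state(1, g0[1], g0[2], g0[3], g0[4])
  k <- 37
  for (i in 1:k) rc <- step_conductances(rc)
  expected <- g0 * exp(-k / RECEPTOR_TAU)
  got <- c(rc$ampa, rc$nmda, rc$gabaa, rc$gabab)
  expect_equal(got, unname(expected), tolerance = 1e-9)
})

test_that("an arrival increases its receptor conductance by exactly the weight", {
  rc <- receptor_state(2)
  rc <- step_conductances(rc, data.frame(neuron = 2, receptor = "nmda",
                                         weight = 0.37))
  expect_equal(rc$nmda, c(0, 0.37))
  expect_equal(rc$ampa, c(0, 0))
  expect_error(
    step_conductances(rc, data.frame(neuron = 1, receptor = "ampa",
                                     weight = -0.1)),
    "negative weight")
})

test_that("the delayed spike buffer delivers at exactly emit + delay", {
  set.seed(42)
  buf <- spike_buffer(50)
  emits <- sample(0:200, 60, replace = TRUE)
  delays <- sample(1:50, 60, replace = TRUE)
  got <- rep(NA_integer_, 60)
  for (t in 0:260) {
    for (d in buffer_pop(buf, t)) got[d$id] <- t
    for (i in which(emits == t)) {
      buffer_push(buf, t, delays[i], list(id = i))
    }
  }
  expect_equal(got, emits + delays)
})

test_that("engine axonal delays are exact for random emit/delay pairs", {
  ## one synapse per (pre, post) pair with a strong weight: the post fires a
  ## fixed integration lag after delivery, so spike-time differences reveal
  ## the delivery step
  set.seed(7)
  n <- 60
  delays <- sample(1:120, n, replace = TRUE)
  emits <- sample(seq(0, 4000, by = 50), n)
  pre <- make_test_group("P", n)
  post <- make_test_group("Q", n)
  pr <- make_test_projection("pq", "P", "Q", 0:(n - 1L), 0:(n - 1L),
                             w = 0.6, delay = delays)
  net <- make_test_network(list(pre, post), list(pr))
  res <- simulate_network(net, forced_spikes("P", emits, 0:(n - 1L)),
                          4500, seed = 1, record = "Q")
  sp <- res$spikes
  lag <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ts <- sp$time_ms[sp$neuron_index == i - 1L]
    lag[i] <- min(ts) - emits[i] - delays[i]
  }
  ## integration lag is a constant independent of emit time and delay
  expect_true(all(!is.na(lag)))
  expect_equal(length(unique(lag)), 1L)
})
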