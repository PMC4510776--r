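test_that("excitatory STDP kernel matches its closed form", {
  expect_equal(estdp_dw(20), 0.1 * exp(-1))
  expect_equal(estdp_dw(-40), -0.07 * exp(-1))
  expect_equal(estdp_dw(0), 0)
  expect_equal(estdp_dw(1e6), 0, tolerance = 1e-12)
  expect_equal(estdp_dw(-1e6), 0, tolerance = 1e-12)
})

test_that("excitatory kernel is strictly decreasing in |dt| on each branch", {
  dts <- seq(1, 200, by = 1)
  ltp <- estdp_dw(dts)
  ltd <- estdp_dw(-dts)
  expect_true(all(diff(ltp) < 0))
  expect_true(all(diff(abs(ltd)) < 0))
  expect_true(all(ltp > 0) && all(ltd < 0))
})

test_that("inhibitory Mexican-hat kernel takes its piecewise values", {
  expect_equal(istdp_dw(3), 0.1)
  expect_equal(istdp_dw(10), -0.06)
  expect_equal(istdp_dw(25), 0)
  expect_equal(istdp_dw(0), 0)   # exact coincidence: open window
  expect_equal(istdp_dw(4), 0.1)    # boundary lambda inclusive
  expect_equal(istdp_dw(20), -0.06) # boundary gamma inclusive
})

test_that("eligibility traces decay with tau_c toward zero", {
  tr <- eligibility_traces(3)
  tr$c <- c(1, -0.5, 0.25)
  pool <- dopamine_pool()
  w <- rep(0.5, 3)
  for (t in 1:1000) {
    out <- step_da_stdp(tr, pool, NULL, 0, w, w_min = 0, w_max = 1)
    tr <- out$traces; pool <- out$pool; w <- out$weights
  }
  expect_equal(tr$c, c(1, -0.5, 0.25) * exp(-1), tolerance = 1e-9)
})

test_that("dopamine pool hits the cap exactly with 475 simultaneous spikes", {
  pool <- dopamine_pool(d = 1)
  pool <- step_dopamine(pool, 475)
  expect_equal(pool$d, 20)
  ## one more spike cannot exceed the cap
  pool <- step_dopamine(pool, 1)
  expect_lte(pool$d, 20)
})

test_that("dopamine concentration never leaves [1, 20] under random bursts", {
  set.seed(3)
  pool <- dopamine_pool()
  for (t in 1:5000) {
    k <- if (runif(1) < 0.01) rpois(1, 300) else rpois(1, 0.3)
    pool <- step_dopamine(pool, k)
    expect_gte(pool$d, 1)
    expect_lte(pool$d, 20)
  }
})

test_that("post-synaptic facilitation gain is affine in d and 1 at baseline", {
  expect_equal(effective_conductance(1, 1), 1)
  expect_equal(effective_conductance(1, 20), 2.9)
  expect_equal(effective_conductance(0, 7), 0)
  d <- seq(1, 20, length.out = 50)
  gain <- effective_conductance(1, d)
  fit <- lm(gain ~ d)
  expect_equal(unname(coef(fit)), c(0.9, 0.1), tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("zero eligibility means no weight change regardless of dopamine", {
  tr <- eligibility_traces(5)
  pool <- dopamine_pool(d = 20)
  w <- runif(5)
  out <- step_da_stdp(tr, pool, NULL, 400, w, w_min = 0, w_max = 1)
  expect_equal(out$weights, w)
})

test_that("with dopamine pinned at baseline, drift follows the accumulated kernel sign", {
  ## one synapse with consistently causal pairings, one anti-causal
  tr <- eligibility_traces(2)
  pool <- dopamine_pool(d = 1)
  w <- c(0.5, 0.5)
  for (rep in 1:20) {
    pairings <- data.frame(synapse = c(1, 2), delta_t = c(15, -15))
    out <- step_da_stdp(tr, pool, pairings, 0, w, w_min = 0, w_max = 1)
    tr <- out$traces; pool <- out$pool; w <- out$weights
    for (t in 1:100) {
      out <- step_da_stdp(tr, pool, NULL, 0, w, w_min = 0, w_max = 1)
      tr <- out$traces; pool <- out$pool; w <- out$weights
    }
  }
  expect_gt(w[1], 0.5)
  expect_lt(w[2], 0.5)
})

test_that("event-driven engine DA-STDP matches dense per-ms integration", {
  ## random pre/post spike trains on plastic synapses; the R oracle
  ## integrates c, d, w on the 1-ms grid with the same nearest-neighbour
  ## pairing rule; weights are compared at the end of the run
  set.seed(11)
  n <- 40
  horizon <- 3000
  pre <- make_test_group("P", n)
  post <- make_test_group("Q", n)
  da <- make_test_group("D", 1, da_source = TRUE)
  delays <- sample(1:10, n, replace = TRUE)
  w0 <- runif(n, 0.001, 0.004)
  pr <- make_test_projection("pq", "P", "Q", 0:(n - 1L), 0:(n - 1L),
                             w = w0, delay = delays,
                             plasticity = "da_stdp", pool = "POOL",
                             w_min = 0, w_max = 0.05,
                             receptor_frac = 1.0)
  pools <- list(POOL = list(tau_d = 50, da_syn = 0.04, baseline = 1,
                            peak = 20, source_group = "D"))
  net <- dawave:::new_network(list(pre, post, da), list(pr), pools,
                              default_config())
  ## schedules: sparse pre/post spikes, occasional DA bursts
  sched <- list()
  for (i in 1:n) {
    sched[[length(sched) + 1]] <- forced_spikes(
      "P", sort(sample(0:(horizon - 20), 12)), i - 1L)
    sched[[length(sched) + 1]] <- forced_spikes(
      "Q", sort(sample(0:(horizon - 20), 12)), i - 1L)
  }
  sched[[length(sched) + 1]] <- forced_spikes(
    "D", rep(c(800, 2000), each = 60), 0L)
  inputs <- do.call(rbind, sched)
  res <- simulate_network(net, inputs, horizon, seed = 5,
                          record = c("P", "Q"), dastdp_on = TRUE)
  ## tiny weights must not evoke extra spikes beyond the forced schedule
  expect_equal(nrow(res$spikes), n * 24)

  ## dense R oracle
  prs <- split(inputs$time_ms[inputs$group == "P"],
               inputs$neuron_index[inputs$group == "P"])
  pos <- split(inputs$time_ms[inputs$group == "Q"],
               inputs$neuron_index[inputs$group == "Q"])
  da_t <- sort(inputs$time_ms[inputs$group == "D"])
  est <- estdp_params()
  w <- w0; cc <- numeric(n); d <- 1
  last_arr <- rep(-Inf, n); last_post <- rep(-Inf, n)
  dec_c <- exp(-1 / 1000); dec_d <- exp(-1 / 50)
  for (t in 0:(horizon - 1)) {
    d <- max(d * dec_d, 1)
    w <- pmin(pmax(w + cc * d, 0), 0.05)
    cc <- cc * dec_c
    for (i in 1:n) {
      if ((t - delays[i]) %in% prs[[as.character(i - 1)]]) {
        ## pre arrival
        if (is.finite(last_post[i])) {
          cc[i] <- cc[i] - est$A_minus *
            exp((last_post[i] - t) / est$tau_minus)
        }
        last_arr[i] <- t
      }
      if (t %in% pos[[as.character(i - 1)]]) {
        if (is.finite(last_arr[i]) && t > last_arr[i]) {
          cc[i] <- cc[i] + est$A_plus *
            exp(-(t - last_arr[i]) / est$tau_plus)
        }
        last_post[i] <- t
      }
    }
    d <- min(d + 0.04 * sum(da_t == t), 20)
  }
  expect_equal(res$network$projections$pq$w, w, tolerance = 1e-6)
})
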