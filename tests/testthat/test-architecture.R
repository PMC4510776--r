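test_that("topographic connection frequencies follow the Gaussian rule", {
  ## many pre neurons at a fixed distance from a single post neuron
  set.seed(31)
  n <- 10000
  pre <- cbind(x = rep(2, n), y = rep(0, n))
  post <- cbind(x = 0, y = 0)
  e <- connect_topographic(pre, post, radius = 2)
  p_hat <- length(e$pre) / n
  p_true <- exp(-0.5)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_hat - p_true), 3 * se)
  ## distance zero connects at the peak probability
  e <- connect_topographic(cbind(x = rep(0, 500), y = 0), post, radius = 2)
  expect_equal(length(e$pre), 500)
  expect_error(connect_topographic(pre[0, , drop = FALSE], post, 2),
               "empty")
})

test_that("degree statistics match the Gaussian profile over distances", {
  set.seed(77)
  pos <- grid_positions(60, 60)
  e <- connect_topographic(pos, pos, radius = 3, exclude_self = TRUE)
  key <- paste(e$pre, e$post)
  for (off in list(c(1, 0), c(2, 2), c(4, 0), c(0, 5))) {
    dx <- off[1]; dy <- off[2]
    ok <- pos[, 1] + dx >= 0 & pos[, 1] + dx < 60 &
      pos[, 2] + dy >= 0 & pos[, 2] + dy < 60
    pre_ids <- which(ok) - 1L
    post_ids <- pre_ids + dx + dy * 60L
    hit <- mean(paste(pre_ids, post_ids) %in% key)
    p <- exp(-(dx^2 + dy^2) / 18)
    se <- sqrt(p * (1 - p) / length(pre_ids))
    expect_lt(abs(hit - p), 4 * se + 1e-9)
  }
})

test_that("built networks respect structural invariants", {
  cfg <- default_config()
  set.seed(3)
  net <- build_network(cfg)
  for (pr in net$projections) {
    expect_true(all(pr$delay >= 1))
    expect_true(all(pr$w >= pr$w_min - 1e-12))
    expect_true(all(pr$w <= pr$w_max + 1e-12))
    if (pr$pre == pr$post) {
      expect_false(any(pr$pre_idx == pr$post_idx))
    }
  }
  ## excitatory lateral delays stay in the configured range
  ee <- net$projections[["pfc_ee:yellow"]]
  expect_true(all(ee$delay >= floor(cfg$projections$pfc_ee$delay_lo)))
  expect_true(all(ee$delay <= ceiling(cfg$projections$pfc_ee$delay_hi)))
})

test_that("default group sizes match the architecture description", {
  cfg <- default_config()
  set.seed(3)
  net <- build_network(cfg)
  expect_equal(net$groups[["PFC:yellow"]]$n, 2048L)
  expect_equal(max(net$groups[["PFC:yellow"]]$positions[, "x"]), 511)
  expect_equal(net$groups$DA$n, 100L)
  expect_equal(net$groups$AG$n, 64L)
  expect_equal(net$groups$TH$n, 288L)
  expect_equal(net$groups[["TH:S1:S2"]]$n, 288L)
})

test_that("network size is stable across wiring seeds", {
  cfg <- default_config()
  sizes <- sapply(c(1, 2, 3), function(s) {
    set.seed(s)
    network_size(build_network(cfg))
  })
  expect_equal(length(unique(sizes)), 1L)
})

test_that("describe_network tabulates groups and projections", {
  cfg <- default_config()
  set.seed(4)
  net <- build_incremental_network(cfg)
  d <- describe_network(net)
  expect_true(all(c("group", "n", "preset") %in% names(d$groups)))
  expect_true("mic_da" %in% d$projections$projection)
  expect_true(all(d$projections$n_syn > 0))
})
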