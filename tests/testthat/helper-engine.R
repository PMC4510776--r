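# Small hand-built networks for engine-level tests.

make_test_group <- function(name, n, preset = "RS", bg_rate = 0,
                            bg_weight = 0, d1_pool = NA_character_,
                            da_source = FALSE) {
  dawave:::make_group(name, n, preset, "cortical", bg_rate = bg_rate,
                      bg_weight = bg_weight, d1_pool = d1_pool,
                      da_source = da_source)
}

make_test_projection <- function(name, pre, post, pre_idx, post_idx, w,
                                 delay, inhibitory = FALSE,
                                 plasticity = "none", pool = NA_character_,
                                 w_min = 0, w_max = 10,
                                 receptor_frac = 1.0) {
  dawave:::make_projection(name, pre, post,
                           list(pre = pre_idx, post = post_idx,
                                dist = rep(NA_real_, length(pre_idx))),
                           w, delay, inhibitory = inhibitory,
                           plasticity = plasticity, pool = pool,
                           w_min = w_min, w_max = w_max,
                           receptor_frac = receptor_frac)
}

make_test_network <- function(groups, projections, pools = list()) {
  dawave:::new_network(groups, projections, pools, default_config())
}

forced_spikes <- function(group, times, idx) {
  data.frame(time_ms = as.integer(times), group = group,
             neuron_index = as.integer(idx))
}
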