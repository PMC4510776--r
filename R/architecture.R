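## Network construction: group layouts, Gaussian topographic / random / full
## projections, delays, plasticity tags, and the adapter that hands a wired
## network to the compiled engine.
##
## Architecture overview (dual-pathway reward circuit):
##   decremental:  AG -> PFC (traveling-wave sheet) -> STR -| DA
##   incremental:  AG -> EXP -> INT -> DA   (conditioned-stimulus route)
##                 TH:S1:S2 / TH -> pIC -> mIC -> DA (hedonic-touch route)
##   DA projects dopamine to the STR and INT pools (DA-STDP + DA-PSF).

#' Grid positions of a row-major layout
#'
#' @param width,height grid dimensions; neuron `i` (0-based) sits at
#'   `(x = i %% width, y = i %/% width)`
#' @return a two-column matrix of positions
#' @export
grid_positions <- function(width, height) {
  idx <- seq_len(width * height) - 1L
  cbind(x = idx %% width, y = idx %/% width)
}

#' Topographic Gaussian connectivity
#'
#' Connection probability between a pre neuron and a post neuron is
#' `peak * exp(-dist^2 / (2 radius^2))` with `dist` the Euclidean distance
#' between their grid positions; candidate pairs farther than
#' `cutoff * radius` are never connected.
#'
#' @param pre_pos,post_pos two-column position matrices (grid units)
#' @param radius Gaussian standard deviation (grid units, > 0)
#' @param peak connection probability at distance zero
#' @param cutoff hard cutoff in units of `radius` (default 3)
#' @param exclude_self drop pairs at exactly distance 0 with equal index
#'   (for recurrent projections on the same layout)
#' @return list with 0-based integer vectors `pre`, `post` and numeric
#'   `dist`
#' @export
connect_topographic <- function(pre_pos, post_pos, radius, peak = 1,
                                cutoff = 3, exclude_self = FALSE) {
  if (nrow(pre_pos) == 0 || nrow(post_pos) == 0) stop("empty layout")
  stopifnot(radius > 0)
  maxd2 <- (cutoff * radius)^2
  pre_out <- integer(0); post_out <- integer(0); dist_out <- numeric(0)
  chunk <- max(1L, as.integer(2e6 / nrow(post_pos)))
  n_pre <- nrow(pre_pos)
  for (s in seq(1L, n_pre, by = chunk)) {
    rows <- s:min(n_pre, s + chunk - 1L)
    dx <- outer(pre_pos[rows, 1], post_pos[, 1], "-")
    dy <- outer(pre_pos[rows, 2], post_pos[, 2], "-")
    d2 <- dx * dx + dy * dy
    p <- peak * exp(-d2 / (2 * radius^2))
    p[d2 > maxd2] <- 0
    if (exclude_self) {
      for (k in seq_along(rows)) {
        j <- rows[k]
        if (j <= nrow(post_pos)) p[k, j] <- 0
      }
    }
    hit <- which(stats::runif(length(p)) < p)
    if (length(hit)) {
      pre_out <- c(pre_out, rows[(hit - 1L) %% length(rows) + 1L] - 1L)
      post_out <- c(post_out, (hit - 1L) %/% length(rows))
      dist_out <- c(dist_out, sqrt(d2[hit]))
    }
  }
  o <- order(pre_out, post_out)
  list(pre = pre_out[o], post = post_out[o], dist = dist_out[o])
}

connect_random <- function(n_pre, n_post, p, exclude_self = FALSE) {
  hit <- which(stats::runif(n_pre * n_post) < p) - 1L
  pre <- hit %% n_pre
  post <- hit %/% n_pre
  if (exclude_self) {
    keep <- pre != post
    pre <- pre[keep]; post <- post[keep]
  }
  o <- order(pre, post)
  list(pre = pre[o], post = post[o], dist = rep(NA_real_, length(pre)))
}

connect_full <- function(n_pre, n_post) {
  list(pre = rep(0:(n_pre - 1L), each = n_post),
       post = rep.int(0:(n_post - 1L), n_pre),
       dist = rep(NA_real_, n_pre * n_post))
}

make_group <- function(name, n, preset, role, width = NA, height = NA,
                       channels = 1L, bg_rate = 0, bg_weight = 0,
                       d1_pool = NA_character_, da_source = FALSE,
                       positions = NULL) {
  p <- neuron_params(preset)
  list(name = name, n = as.integer(n), preset = preset, role = role,
       width = width, height = height, channels = as.integer(channels),
       params = p, inhibitory = identical(preset, "FS"),
       bg_rate = bg_rate, bg_weight = bg_weight,
       d1_pool = d1_pool, da_source = da_source, positions = positions)
}

make_projection <- function(name, pre, post, edges, w, delay,
                            inhibitory, plasticity = "none",
                            pool = NA_character_, w_min = 0, w_max = Inf,
                            receptor_frac = 0.5, params = list()) {
  n <- length(edges$pre)
  list(name = name, pre = pre, post = post,
       pre_idx = as.integer(edges$pre), post_idx = as.integer(edges$post),
       w = rep_len(as.numeric(w), n),
       delay = as.integer(rep_len(delay, n)),
       inhibitory = inhibitory, plasticity = plasticity, pool = pool,
       w_min = w_min, w_max = w_max, receptor_frac = receptor_frac,
       params = params)
}

## Excitatory lateral conductance delays, drawn uniformly in
## [delay_lo, delay_hi] ms.  Near-synchronous arrival of one wavefront's
## spikes at the next band is what makes the hop-by-hop wave speed stable;
## the hop distance (set by the Gaussian radius and weights) divided by the
## mean delay gives the traversal speed.
lateral_delays <- function(dist, delay_lo, delay_hi) {
  pmax(1L, as.integer(round(stats::runif(length(dist), delay_lo, delay_hi))))
}

pfc_channel_groups <- function(ch, cfg) {
  g <- cfg$groups$pfc
  exc_pos <- grid_positions(g$width, g$height)
  inh_pos <- cbind(x = seq_len(g$inh_n) - 1L,
                   y = rep((g$height - 1) / 2, g$inh_n))
  list(
    exc = make_group(paste0("PFC:", ch), g$width * g$height, "RS",
                     "cortical", g$width, g$height,
                     bg_rate = g$bg_rate, bg_weight = g$bg_weight,
                     positions = exc_pos),
    inh = make_group(paste0("PFCi:", ch), g$inh_n, "FS", "cortical",
                     bg_rate = 0, bg_weight = 0, positions = inh_pos)
  )
}

pfc_channel_projections <- function(ch, cfg) {
  p <- cfg$projections
  pl <- cfg$plasticity
  exc <- paste0("PFC:", ch); inh <- paste0("PFCi:", ch)
  g <- cfg$groups$pfc
  ## all PFC channels of a given geometry share one realized lateral wiring
  ## (drawn from a dedicated stream), so lateral weights developed on a
  ## standalone sheet can be installed into any channel of a full network
  set.seed(substream_seed(cfg$rng_seed, paste0("pfc_wiring_h", g$height)))
  ## lateral weights are tuned to match the number of presynaptic partners:
  ## in-degree grows with sheet height, so per-synapse weights scale down;
  ## conduction delays are tuned to keep the traversal timing stable across
  ## heights (the residual geometry effect is absorbed by a small delay
  ## adjustment)
  hs <- 4 / g$height
  ds <- (4 / g$height)^0.225
  exc_pos <- grid_positions(g$width, g$height)
  inh_pos <- cbind(x = seq_len(g$inh_n) - 1L,
                   y = rep((g$height - 1) / 2, g$inh_n))
  ee <- connect_topographic(exc_pos, exc_pos, p$pfc_ee$radius,
                            exclude_self = TRUE)
  ei <- connect_topographic(exc_pos, inh_pos, p$pfc_ei$radius)
  ie <- connect_topographic(inh_pos, exc_pos, p$pfc_ie$radius)
  list(
    make_projection(paste0("pfc_ee:", ch), exc, exc, ee,
                    p$pfc_ee$w_init * hs,
                    lateral_delays(ee$dist, p$pfc_ee$delay_lo * ds,
                                   p$pfc_ee$delay_hi * ds),
                    inhibitory = FALSE, plasticity = "estdp",
                    w_min = p$pfc_ee$w_min * hs,
                    w_max = p$pfc_ee$w_max * hs,
                    receptor_frac = p$pfc_ee$ampa_frac,
                    params = pl$estdp),
    make_projection(paste0("pfc_ei:", ch), exc, inh, ei, p$pfc_ei$w * hs,
                    p$pfc_ei$delay, inhibitory = FALSE,
                    receptor_frac = p$pfc_ei$ampa_frac),
    make_projection(paste0("pfc_ie:", ch), inh, exc, ie, p$pfc_ie$w_init,
                    p$pfc_ie$delay, inhibitory = TRUE,
                    plasticity = "istdp", w_min = p$pfc_ie$w_min,
                    w_max = p$pfc_ie$w_max,
                    receptor_frac = p$pfc_ie$gabaa_frac,
                    params = pl$istdp)
  )
}

#' Build a standalone traveling-wave sheet (one PFC channel)
#'
#' A single excitatory grid of `width x height` regular-spiking neurons
#' plus its fast-spiking pool, laterally wired with Gaussian
#' excitatory/inhibitory radii and distance-scaled conductance delays.
#' Used for wave development and probe experiments without the rest of the
#' circuit.
#'
#' @param config a configuration list (see [default_config()])
#' @param height optional override of the sheet height (number of rows)
#' @return an `snn_network`
#' @export
build_pfc_sheet <- function(config = default_config(), height = NULL) {
  if (!is.null(height)) config$groups$pfc$height <- height
  gg <- pfc_channel_groups("probe", config)
  pp <- pfc_channel_projections("probe", config)
  new_network(list(gg$exc, gg$inh), pp, pools = list(), config)
}

new_network <- function(groups, projections, pools, config) {
  names(groups) <- vapply(groups, `[[`, "", "name")
  names(projections) <- vapply(projections, `[[`, "", "name")
  offsets <- c(0, cumsum(vapply(groups, `[[`, 0L, "n")))
  for (pr in projections) {
    stopifnot(pr$pre %in% names(groups), pr$post %in% names(groups))
    stopifnot(all(pr$delay >= 0))
    stopifnot(all(pr$w >= pr$w_min - 1e-12), all(pr$w <= pr$w_max + 1e-12))
    if (pr$plasticity == "da_stdp") stopifnot(pr$pool %in% names(pools))
  }
  structure(list(groups = groups, projections = projections,
                 pools = pools, offsets = offsets[-length(offsets)],
                 config = config),
            class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat("<snn_network>", length(x$groups), "groups,",
      length(x$projections), "projections,",
      network_size(x), "neurons,",
      sum(vapply(x$projections, function(p) length(p$pre_idx), 0L)),
      "synapses\n")
  invisible(x)
}

#' Total neuron count of a network
#' @param network an `snn_network`
#' @export
network_size <- function(network) {
  sum(vapply(network$groups, `[[`, 0L, "n"))
}

#' Realized group and projection table
#'
#' @param network an `snn_network`
#' @return list of two data.frames, `groups` and `projections`
#' @export
describe_network <- function(network) {
  g <- do.call(rbind, lapply(network$groups, function(gr) {
    data.frame(group = gr$name, n = gr$n, preset = gr$preset,
               role = gr$role, bg_rate_hz = gr$bg_rate)
  }))
  p <- do.call(rbind, lapply(network$projections, function(pr) {
    data.frame(projection = pr$name, pre = pr$pre, post = pr$post,
               n_syn = length(pr$pre_idx),
               w_mean = if (length(pr$w)) mean(pr$w) else NA_real_,
               plasticity = pr$plasticity,
               inhibitory = pr$inhibitory)
  }))
  rownames(g) <- rownames(p) <- NULL
  list(groups = g, projections = p)
}

#' Build the full dual-pathway network
#'
#' Wires the complete circuit from the configuration: per-color AG input
#' channels feeding the PFC traveling-wave sheets (200-ms axonal delay) and
#' the EXP experience pool; plastic (dopamine-modulated) PFC->STR and
#' EXP->INT projections; inhibitory STR->DA; the tactile route with fast
#' topographic TH:S1:S2->pIC and slow full TH->pIC per direction channel;
#' pIC lateral wiring and mIC shunting feedback; mIC->DA and INT->DA
#' excitation; and dopaminergic DA->STR / DA->INT pools.
#'
#' Uses the R random number generator for connectivity; seed with
#' [set.seed()].
#'
#' @param config configuration list, see [default_config()]
#' @return an `snn_network`
#' @export
build_network <- function(config = default_config()) {
  cfg <- config
  ## wiring is drawn from a dedicated stream of the configured rng_seed:
  ## the realized network is part of the model specification, and changing
  ## experiment seeds varies inputs and noise, not the anatomy
  set.seed(substream_seed(cfg$rng_seed, "wiring"))
  ch <- cfg$channels
  dirs <- c("up", "down", "left", "right")
  gcfg <- cfg$groups
  p <- cfg$projections
  pl <- cfg$plasticity
  nch <- length(ch)
  grid_n <- 72L  # 9 x 8 trackball layout per direction channel

  groups <- list()
  projections <- list()

  ## --- input and experience groups ------------------------------------
  ag <- make_group("AG", gcfg$ag$n_per_channel * nch, "RS", "input",
                   channels = nch)
  exp_g <- make_group("EXP", gcfg$exp$n_per_channel * nch, "RS", "cortical",
                      channels = nch, bg_rate = gcfg$exp$bg_rate,
                      bg_weight = gcfg$exp$bg_weight)
  th <- make_group("TH", grid_n * 4L, "RS", "input", 9, 8, channels = 4L)
  ths <- make_group("TH:S1:S2", grid_n * 4L, "RS", "input", 9, 8,
                    channels = 4L)
  groups <- c(groups, list(ag, exp_g, th, ths))

  ## --- PFC channels -----------------------------------------------------
  for (cc in ch) {
    gg <- pfc_channel_groups(cc, cfg)
    groups <- c(groups, list(gg$exc, gg$inh))
    projections <- c(projections, pfc_channel_projections(cc, cfg))
  }

  ## --- striatum, INT, insula, dopamine ---------------------------------
  str_g <- make_group("STR", gcfg$str$n, "FS", "striatal",
                      bg_rate = gcfg$str$bg_rate,
                      bg_weight = gcfg$str$bg_weight, d1_pool = "STR")
  int_g <- make_group("INT", gcfg$int$n, "RS", "cortical",
                      bg_rate = gcfg$int$bg_rate,
                      bg_weight = gcfg$int$bg_weight, d1_pool = "INT")
  pic <- make_group("pIC", grid_n * 4L, "RS", "cortical", 9, 8,
                    channels = 4L, bg_rate = gcfg$pic$bg_rate,
                    bg_weight = gcfg$pic$bg_weight)
  pici_n <- as.integer(round(grid_n * gcfg$pic$inh_frac))
  pici <- make_group("pICi", pici_n * 4L, "FS", "cortical", channels = 4L)
  mic <- make_group("mIC", gcfg$mic$n, "RS", "cortical",
                    bg_rate = gcfg$mic$bg_rate,
                    bg_weight = gcfg$mic$bg_weight)
  da <- make_group("DA", gcfg$da$n, "RS", "dopaminergic",
                   bg_rate = gcfg$da$bg_rate, bg_weight = gcfg$da$bg_weight,
                   da_source = TRUE)
  groups <- c(groups, list(str_g, int_g, pic, pici, mic, da))

  str_pos <- cbind(x = seq_len(gcfg$str$n) - 1L,
                   y = rep((gcfg$pfc$height - 1) / 2, gcfg$str$n))

  ## --- decremental pathway ---------------------------------------------
  for (ci in seq_along(ch)) {
    cc <- ch[ci]
    nag <- gcfg$ag$n_per_channel
    ## AG channel neurons occupy a block at the left edge of their sheet
    ag_pos <- cbind(x = (seq_len(nag) - 1L) %% 4L,
                    y = ((seq_len(nag) - 1L) %/% 4L) %%
                      gcfg$pfc$height)
    pfc_pos <- grid_positions(gcfg$pfc$width, gcfg$pfc$height)
    e <- connect_topographic(ag_pos, pfc_pos, p$ag_pfc$radius)
    e$pre <- e$pre + (ci - 1L) * nag     # channel-stacked AG indices
    projections <- c(projections, list(
      make_projection(paste0("ag_pfc:", cc), "AG", paste0("PFC:", cc), e,
                      p$ag_pfc$w, p$ag_pfc$delay, inhibitory = FALSE,
                      receptor_frac = p$ag_pfc$ampa_frac)))
    e2 <- connect_topographic(pfc_pos, str_pos, p$pfc_str$radius)
    projections <- c(projections, list(
      make_projection(paste0("pfc_str:", cc), paste0("PFC:", cc), "STR",
                      e2, p$pfc_str$w_init, p$pfc_str$delay,
                      inhibitory = FALSE, plasticity = "da_stdp",
                      pool = "STR", w_min = p$pfc_str$w_min,
                      w_max = p$pfc_str$w_max,
                      receptor_frac = p$pfc_str$ampa_frac,
                      params = pl$estdp)))
  }
  e <- connect_random(str_g$n, da$n, p$str_da$p)
  projections <- c(projections, list(
    make_projection("str_da", "STR", "DA", e, p$str_da$w, p$str_da$delay,
                    inhibitory = TRUE,
                    receptor_frac = p$str_da$gabaa_frac)))

  ## --- incremental pathway for the CS -----------------------------------
  nexp <- gcfg$exp$n_per_channel
  for (ci in seq_along(ch)) {
    nag <- gcfg$ag$n_per_channel
    e <- connect_random(nag, nexp, p$ag_exp$p)
    e$pre <- e$pre + (ci - 1L) * nag
    e$post <- e$post + (ci - 1L) * nexp
    projections <- c(projections, list(
      make_projection(paste0("ag_exp:", ch[ci]), "AG", "EXP", e,
                      p$ag_exp$w, p$ag_exp$delay, inhibitory = FALSE,
                      receptor_frac = p$ag_exp$ampa_frac)))
  }
  e <- connect_random(exp_g$n, int_g$n, p$exp_int$p)
  projections <- c(projections, list(
    make_projection("exp_int", "EXP", "INT", e, p$exp_int$w_init,
                    p$exp_int$delay, inhibitory = FALSE,
                    plasticity = "da_stdp", pool = "INT",
                    w_min = p$exp_int$w_min, w_max = p$exp_int$w_max,
                    receptor_frac = p$exp_int$ampa_frac,
                    params = pl$estdp)))
  e <- connect_random(int_g$n, da$n, p$int_da$p)
  projections <- c(projections, list(
    make_projection("int_da", "INT", "DA", e, p$int_da$w, p$int_da$delay,
                    inhibitory = FALSE,
                    receptor_frac = p$int_da$ampa_frac)))

  ## --- incremental pathway for the US (tactile) -------------------------
  grid_pos <- grid_positions(9, 8)
  pici_pos <- cbind(x = rep(0:8, length.out = pici_n),
                    y = rep(c(2, 5), each = 9, length.out = pici_n))
  for (di in 1:4) {
    dd <- dirs[di]
    off_g <- (di - 1L) * grid_n
    off_i <- (di - 1L) * pici_n
    shift <- function(e, po, qo) {
      e$pre <- e$pre + po; e$post <- e$post + qo; e
    }
    w_th <- cfg$projections$th_pic$w[[dd]]
    e <- connect_topographic(grid_pos, grid_pos, p$ths_pic$radius)
    projections <- c(projections, list(
      make_projection(paste0("ths_pic:", dd), "TH:S1:S2", "pIC",
                      shift(e, off_g, off_g), p$ths_pic$w, p$ths_pic$delay,
                      inhibitory = FALSE,
                      receptor_frac = p$ths_pic$ampa_frac)))
    ## dense random fan-out: spatially unstructured like a full projection
    ## (the slow pathway carries no somatotopy) but sparse enough that
    ## drive fluctuations decorrelate across pIC neurons
    e <- connect_random(grid_n, grid_n, p$th_pic$p)
    projections <- c(projections, list(
      make_projection(paste0("th_pic:", dd), "TH", "pIC",
                      shift(e, off_g, off_g), w_th, p$th_pic$delay,
                      inhibitory = FALSE,
                      receptor_frac = p$th_pic$ampa_frac)))
    e <- connect_random(grid_n, pici_n, p$th_pic$p)
    projections <- c(projections, list(
      make_projection(paste0("th_pici:", dd), "TH", "pICi",
                      shift(e, off_g, off_i),
                      w_th * p$th_pici$w_scale, p$th_pic$delay,
                      inhibitory = FALSE,
                      receptor_frac = p$th_pic$ampa_frac)))
    ## feedforward inhibition from the fast pathway: its strength does not
    ## scale with the slow-pathway weight, which is what makes the
    ## dopamine-burst probability a steep function of that weight
    e <- connect_full(grid_n, pici_n)
    projections <- c(projections, list(
      make_projection(paste0("ths_pici:", dd), "TH:S1:S2", "pICi",
                      shift(e, off_g, off_i), p$ths_pici$w,
                      p$ths_pic$delay, inhibitory = FALSE,
                      receptor_frac = p$ths_pici$ampa_frac)))
    e <- connect_topographic(grid_pos, grid_pos, p$pic_ee$radius,
                             exclude_self = TRUE)
    projections <- c(projections, list(
      make_projection(paste0("pic_ee:", dd), "pIC", "pIC",
                      shift(e, off_g, off_g), p$pic_ee$w, p$pic_ee$delay,
                      inhibitory = FALSE,
                      receptor_frac = p$pic_ee$ampa_frac)))
    e <- connect_topographic(grid_pos, pici_pos, p$pic_ei$radius)
    projections <- c(projections, list(
      make_projection(paste0("pic_ei:", dd), "pIC", "pICi",
                      shift(e, off_g, off_i), p$pic_ei$w, p$pic_ei$delay,
                      inhibitory = FALSE,
                      receptor_frac = p$pic_ei$ampa_frac)))
    e <- connect_topographic(pici_pos, grid_pos, p$pic_ie$radius)
    projections <- c(projections, list(
      make_projection(paste0("pic_ie:", dd), "pICi", "pIC",
                      shift(e, off_i, off_g), p$pic_ie$w, p$pic_ie$delay,
                      inhibitory = TRUE,
                      receptor_frac = p$pic_ie$gabaa_frac)))
    e <- connect_random(grid_n, mic$n, p$pic_mic$p)
    projections <- c(projections, list(
      make_projection(paste0("pic_mic:", dd), "pIC", "mIC",
                      shift(e, off_g, 0L), p$pic_mic$w, p$pic_mic$delay,
                      inhibitory = FALSE,
                      receptor_frac = p$pic_mic$ampa_frac)))
    e <- connect_random(mic$n, pici_n, p$mic_pici$p)
    projections <- c(projections, list(
      make_projection(paste0("mic_pici:", dd), "mIC", "pICi",
                      shift(e, 0L, off_i), p$mic_pici$w, p$mic_pici$delay,
                      inhibitory = FALSE,
                      receptor_frac = p$mic_pici$ampa_frac)))
  }
  e <- connect_random(mic$n, da$n, p$mic_da$p)
  ## standalone tactile subnetworks omit the tonic striatal inhibition that
  ## tempers dopaminergic excitability in the full circuit, so the mIC->DA
  ## drive carries a separate calibration for that configuration
  w_mda <- if (isTRUE(cfg$subnet_tactile)) p$mic_da$w_subnet else p$mic_da$w
  projections <- c(projections, list(
    make_projection("mic_da", "mIC", "DA", e, w_mda, p$mic_da$delay,
                    inhibitory = FALSE,
                    receptor_frac = p$mic_da$ampa_frac)))

  pools <- list(
    STR = list(tau_d = pl$da_pool$tau_d, da_syn = pl$da_pool$da_syn,
               baseline = pl$da_pool$baseline, peak = pl$da_pool$peak,
               source_group = "DA"),
    INT = list(tau_d = pl$da_pool$tau_d, da_syn = pl$da_pool$da_syn,
               baseline = pl$da_pool$baseline, peak = pl$da_pool$peak,
               source_group = "DA")
  )
  if (!isTRUE(cfg$plasticity$psf_int)) {
    int_g$d1_pool <- NA_character_
  }
  new_network(groups, projections, pools, cfg)
}

#' Build the incremental-pathway subnetwork (tactile route only)
#'
#' TH, TH:S1:S2, pIC, pICi, mIC and DA with their projections — the
#' subcircuit used for burst-probability sweeps over the slow-pathway
#' weights.
#'
#' @param config configuration list
#' @param th_pic_w optional named list/vector of per-direction
#'   TH->pIC weights (e.g. `list(up = 0.03, right = 0.04, ...)`)
#' @return an `snn_network`
#' @export
build_incremental_network <- function(config = default_config(),
                                      th_pic_w = NULL) {
  cfg <- config
  if (!is.null(th_pic_w)) {
    for (d in names(th_pic_w)) cfg$projections$th_pic$w[[d]] <- th_pic_w[[d]]
  }
  cfg$channels <- character(0)
  cfg$subnet_tactile <- TRUE
  net <- build_network_tactile_only(cfg)
  net
}

build_network_tactile_only <- function(cfg) {
  ## reuse build_network but strip decremental groups by building with no
  ## color channels; AG/EXP/INT/STR remain as minimal stubs so the DA pools
  ## and INT->DA exist, but they stay silent without CS input.
  full <- build_network(cfg)
  keep <- c("TH", "TH:S1:S2", "pIC", "pICi", "mIC", "DA")
  groups <- full$groups[keep]
  pnames <- names(full$projections)
  keep_p <- vapply(full$projections, function(pr) {
    pr$pre %in% keep && pr$post %in% keep
  }, TRUE)
  projections <- full$projections[keep_p]
  new_network(groups, projections, full$pools, cfg)
}

## ---------------------------------------------------------------------
## engine adapter

as_engine_net <- function(network, record = character()) {
  groups <- lapply(network$groups, function(g) {
    d1 <- if (is.na(g$d1_pool)) -1L else
      match(g$d1_pool, names(network$pools)) - 1L
    list(n = g$n, a = g$params$a, b = g$params$b, c = g$params$c_reset,
         d = g$params$d_jump, record = g$name %in% record,
         bg_rate = g$bg_rate, bg_weight = g$bg_weight,
         d1_pool = d1, da_source = g$da_source)
  })
  offs <- network$offsets
  names(offs) <- names(network$groups)
  projections <- lapply(network$projections, function(pr) {
    pcode <- match(pr$plasticity, c("none", "estdp", "istdp", "da_stdp")) - 1L
    par <- pr$params
    defaults <- list(A_plus = 0.1, A_minus = 0.07, tau_plus = 20,
                     tau_minus = 40, B_plus = 0.1, B_minus = 0.06,
                     lambda_win = 4, gamma_win = 20, tau_c = 1000)
    for (k in names(defaults)) {
      if (is.null(par[[k]])) par[[k]] <- defaults[[k]]
    }
    list(pre = pr$pre_idx + offs[[pr$pre]],
         post = pr$post_idx + offs[[pr$post]],
         w = pr$w, delay = pr$delay,
         A_plus = par$A_plus, A_minus = par$A_minus,
         tau_plus = par$tau_plus, tau_minus = par$tau_minus,
         B_plus = par$B_plus, B_minus = par$B_minus,
         lambda_win = par$lambda_win, gamma_win = par$gamma_win,
         w_min = pr$w_min, w_max = min(pr$w_max, 1e6),
         tau_c = par$tau_c, plasticity_code = pcode,
         pool_index = if (is.na(pr$pool)) -1L else
           match(pr$pool, names(network$pools)) - 1L,
         inhibitory = pr$inhibitory, receptor_frac = pr$receptor_frac)
  })
  pools <- lapply(network$pools, function(pl) {
    list(tau_d = pl$tau_d, da_syn = pl$da_syn, baseline = pl$baseline,
         peak = pl$peak,
         source_group = match(pl$source_group, names(network$groups)) - 1L)
  })
  list(groups = unname(groups), projections = unname(projections),
       pools = unname(pools))
}

#' Run the compiled engine on a wired network
#'
#' Integrates the whole network on the 1-ms grid: conductance decay,
#' delayed spike delivery, background Poisson drive, membrane half-steps,
#' spike detection/reset, the enabled plasticity rules, and dopamine-pool
#' updates.  State (membranes, conductances, traces) starts at rest;
#' weights are carried in and out through the network object.
#'
#' @param network an `snn_network`
#' @param inputs `NULL` or a spike-log data.frame (`time_ms`, `group`,
#'   `neuron_index`) of scheduled source spikes (forced firings)
#' @param duration_ms simulated time (ms)
#' @param seed integer seed for the engine's private RNG (background noise)
#' @param record character vector of group names whose spikes to log
#' @param estdp_on enable E-STDP / I-STDP updates
#' @param dastdp_on enable dopamine-modulated STDP
#' @param da_trace record per-ms dopamine pool concentrations
#' @return list with `spikes` (data.frame `time_ms`, `group`,
#'   `neuron_index`), `network` (weights updated), `counts` (named
#'   per-group spike counts), `pool_trace`, `pool_final`
#' @export
simulate_network <- function(network, inputs = NULL, duration_ms,
                             seed = 1, record = character(),
                             estdp_on = FALSE, dastdp_on = FALSE,
                             da_trace = FALSE) {
  en <- as_engine_net(network, record)
  if (is.null(inputs) || nrow(inputs) == 0) {
    in_t <- integer(0); in_id <- integer(0)
  } else {
    gi <- match(inputs$group, names(network$groups))
    if (anyNA(gi)) {
      stop("unknown input group: ",
           paste(unique(inputs$group[is.na(gi)]), collapse = ", "))
    }
    bad <- inputs$neuron_index < 0 |
      inputs$neuron_index >= vapply(network$groups, `[[`, 0L, "n")[gi]
    if (any(bad)) stop("input neuron_index out of range")
    o <- order(inputs$time_ms)
    in_t <- as.integer(inputs$time_ms[o])
    in_id <- as.integer(network$offsets[gi][o] + inputs$neuron_index[o])
  }
  res <- run_engine(en, in_t, in_id, as.integer(duration_ms),
                    as.integer(seed),
                    list(estdp_on = estdp_on, dastdp_on = dastdp_on,
                         da_trace = da_trace))
  for (i in seq_along(network$projections)) {
    network$projections[[i]]$w <- res$weights[[i]]
  }
  gname <- names(network$groups)
  gidx <- findInterval(res$spike_id, network$offsets)
  spikes <- data.frame(time_ms = res$spike_t,
                       group = unname(gname[gidx]),
                       neuron_index = res$spike_id -
                         network$offsets[gidx])
  counts <- as.numeric(res$group_spike_counts)
  names(counts) <- gname
  list(spikes = spikes, network = network, counts = counts,
       pool_trace = res$pool_trace, pool_final = res$pool_final)
}
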