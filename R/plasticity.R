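## The four learning rules: excitatory STDP, Mexican-hat inhibitory STDP,
## eligibility-trace dopamine-modulated STDP, and dopamine-gated
## post-synaptic facilitation.
##
## Pairing convention everywhere: nearest neighbour.  t_pre is the arrival
## time of the *last* pre-synaptic spike at the synapse (axonal delay
## included) and t_post the time of the last post-synaptic spike.

#' Excitatory STDP parameters
#'
#' Defaults: potentiation amplitude `A_plus = 0.1` with time constant
#' `tau_plus = 20` ms; depression amplitude `A_minus = 0.07` with
#' `tau_minus = 40` ms.
#' @param A_plus,A_minus kernel amplitudes (weight units)
#' @param tau_plus,tau_minus kernel decay constants (ms)
#' @export
estdp_params <- function(A_plus = 0.1, A_minus = 0.07,
                         tau_plus = 20, tau_minus = 40) {
  structure(list(A_plus = A_plus, A_minus = A_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus),
            class = "estdp_params")
}

#' Inhibitory (Mexican-hat) STDP parameters
#'
#' Piecewise-constant kernel on `|t_post - t_pre|`: potentiation `B_plus`
#' inside `(0, lambda_win]`, depression `B_minus` inside
#' `(lambda_win, gamma_win]`, zero outside.  Defaults
#' `(0.1, 0.06, 4, 20)`.
#' @param B_plus,B_minus amplitudes (weight units)
#' @param lambda_win,gamma_win LTP/LTD window bounds (ms),
#'   `lambda_win < gamma_win`
#' @export
istdp_params <- function(B_plus = 0.1, B_minus = 0.06,
                         lambda_win = 4, gamma_win = 20) {
  stopifnot(lambda_win < gamma_win)
  structure(list(B_plus = B_plus, B_minus = B_minus,
                 lambda_win = lambda_win, gamma_win = gamma_win),
            class = "istdp_params")
}

#' Excitatory STDP kernel
#'
#' Signed weight change for a pre/post pairing with
#' `delta_t = t_post - t_pre` (ms): `+A_plus * exp(-delta_t / tau_plus)`
#' for pre-before-post, `-A_minus * exp(delta_t / tau_minus)` for
#' post-before-pre, and exactly zero at coincidence.
#'
#' @param delta_t `t_post - t_pre` in ms (vectorised)
#' @param params an `estdp_params`
#' @return signed weight change(s)
#' @export
estdp_dw <- function(delta_t, params = estdp_params()) {
  out <- numeric(length(delta_t))
  ltp <- delta_t > 0
  ltd <- delta_t < 0
  out[ltp] <- params$A_plus * exp(-delta_t[ltp] / params$tau_plus)
  out[ltd] <- -params$A_minus * exp(delta_t[ltd] / params$tau_minus)
  out
}

#' Inhibitory STDP kernel
#'
#' Mexican-hat window on the absolute pairing interval: `+B_plus` for
#' `0 < |dt| <= lambda_win`, `-B_minus` for `lambda_win < |dt| <=
#' gamma_win`, zero otherwise (including exact coincidence).
#'
#' @param abs_delta_t `|t_post - t_pre|` in ms (vectorised, non-negative)
#' @param params an `istdp_params`
#' @return signed weight change(s)
#' @export
istdp_dw <- function(abs_delta_t, params = istdp_params()) {
  stopifnot(all(abs_delta_t >= 0))
  out <- numeric(length(abs_delta_t))
  out[abs_delta_t > 0 & abs_delta_t <= params$lambda_win] <- params$B_plus
  out[abs_delta_t > params$lambda_win &
        abs_delta_t <= params$gamma_win] <- -params$B_minus
  out
}

#' Dopamine pool for one modulated group
#'
#' Concentration `d` (micromolar) decays with `tau_d = 50` ms, gains
#' `da_syn = 0.04` per afferent dopaminergic spike, and is clamped to the
#' physiological range `[baseline, peak] = [1, 20]`.
#'
#' @param d initial concentration
#' @param tau_d decay constant (ms)
#' @param da_syn increment per dopaminergic spike
#' @param baseline,peak clamp bounds
#' @export
dopamine_pool <- function(d = 1, tau_d = 50, da_syn = 0.04,
                          baseline = 1, peak = 20) {
  structure(list(d = d, tau_d = tau_d, da_syn = da_syn,
                 baseline = baseline, peak = peak),
            class = "dopamine_pool")
}

#' Advance a dopamine pool by one step
#'
#' Order of operations: exponential decay toward zero, reflecting floor at
#' the baseline, addition of `da_syn` per arriving dopaminergic spike, cap
#' at the peak.
#'
#' @param pool a `dopamine_pool`
#' @param da_spike_count dopaminergic spikes arriving this step
#' @param dt step (ms)
#' @return the updated pool
#' @export
step_dopamine <- function(pool, da_spike_count = 0, dt = 1) {
  d <- pool$d * exp(-dt / pool$tau_d)
  d <- max(d, pool$baseline)
  d <- d + pool$da_syn * da_spike_count
  pool$d <- min(d, pool$peak)
  pool
}

#' Dopamine-gated post-synaptic facilitation
#'
#' Effective conductance `g * (0.9 + 0.1 d)`, applied at
#' current-computation time to the AMPA and NMDA conductances of
#' D1-receptor-bearing groups.  The gain is exactly 1 at the 1 uM baseline
#' and 2.9 at the 20 uM peak.
#'
#' @param g conductance(s)
#' @param d dopamine concentration (uM, in `[1, 20]`)
#' @return the effective conductance
#' @export
effective_conductance <- function(g, d) {
  stopifnot(d >= 1, d <= 20)
  g * (0.9 + 0.1 * d)
}

#' Eligibility traces for a dopamine-modulated projection
#'
#' @param n number of plastic synapses
#' @param tau_c trace decay constant (ms), default 1000
#' @export
eligibility_traces <- function(n, tau_c = 1000) {
  structure(list(c = numeric(n), tau_c = tau_c),
            class = "eligibility_traces")
}

#' One step of eligibility-trace dopamine-modulated STDP
#'
#' Dense per-ms reference integrator.  Traces decay with `tau_c` and
#' accumulate the excitatory STDP kernel for each pairing detected this
#' step; the dopamine pool is advanced by [step_dopamine()]; weights then
#' advance by `c * d * dt` and are clipped to their bounds.
#'
#' @param traces an `eligibility_traces`
#' @param pool a `dopamine_pool`
#' @param pairings `NULL` or data.frame with columns `synapse` (1-based)
#'   and `delta_t` (= t_post - t_pre, ms)
#' @param da_spike_count dopaminergic spikes arriving this step
#' @param weights current weights (length matches traces)
#' @param w_min,w_max clipping bounds
#' @param dt step (ms)
#' @param estdp kernel parameters for the pairing contribution
#' @return `list(traces, pool, weights)`
#' @export
step_da_stdp <- function(traces, pool, pairings = NULL, da_spike_count = 0,
                         weights, w_min = 0, w_max = Inf, dt = 1,
                         estdp = estdp_params()) {
  traces$c <- traces$c * exp(-dt / traces$tau_c)
  if (!is.null(pairings) && nrow(pairings) > 0) {
    dw <- estdp_dw(pairings$delta_t, estdp)
    for (i in seq_len(nrow(pairings))) {
      s <- pairings$synapse[i]
      traces$c[s] <- traces$c[s] + dw[i]
    }
  }
  pool <- step_dopamine(pool, da_spike_count, dt)
  weights <- weights + traces$c * pool$d * dt
  weights <- pmin(pmax(weights, w_min), w_max)
  if (any(weights < w_min - 1e-12) || any(weights > w_max + 1e-12)) {
    stop("internal error: weight bounds violated after clipping")
  }
  list(traces = traces, pool = pool, weights = weights)
}
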