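## Izhikevich membrane dynamics and four-receptor conductance synapses.
##
## These functions define the reference semantics of one integration step on
## the 1-ms grid.  The compiled engine (simulate_network) implements the same
## update order for whole networks; these R versions operate on small state
## vectors and are the ones documented and unit-tested against closed forms.

#' Spike threshold of the Izhikevich model (mV)
#' @export
IZH_SPIKE_THRESHOLD <- 30

#' Receptor conductance decay constants (ms)
#'
#' Named vector of exponential decay constants for the four receptor
#' channels: AMPA 5 ms, NMDA 100 ms, GABA_A 6 ms, GABA_B 150 ms.
#' @export
RECEPTOR_TAU <- c(ampa = 5, nmda = 100, gabaa = 6, gabab = 150)

#' Izhikevich neuron parameters
#'
#' Two presets are used throughout: regular-spiking (RS) excitatory cells
#' `(a, b, c, d) = (0.02, 0.2, -65, 8)` and fast-spiking (FS) inhibitory
#' cells `(0.1, 0.2, -65, 2)`.
#'
#' @param preset `"RS"` or `"FS"`, or `NULL` to pass the four values
#'   directly.
#' @param a recovery time scale (1/ms)
#' @param b recovery sensitivity (dimensionless)
#' @param c_reset post-spike membrane reset (mV)
#' @param d_jump post-spike recovery increment
#' @return an object of class `neuron_params`
#' @examples
#' neuron_params("RS")
#' @export
neuron_params <- function(preset = NULL, a = 0.02, b = 0.2,
                          c_reset = -65, d_jump = 8) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("RS", "FS"))
    if (preset == "RS") {
      a <- 0.02; b <- 0.2; c_reset <- -65; d_jump <- 8
    } else {
      a <- 0.1; b <- 0.2; c_reset <- -65; d_jump <- 2
    }
  }
  structure(list(a = a, b = b, c_reset = c_reset, d_jump = d_jump),
            class = "neuron_params")
}

#' Membrane state of a neuron population
#'
#' @param v membrane potentials (mV)
#' @param u recovery currents
#' @return an object of class `membrane_state`
#' @export
membrane_state <- function(v, u) {
  stopifnot(length(v) == length(u))
  structure(list(v = as.numeric(v), u = as.numeric(u)),
            class = "membrane_state")
}

#' Resting state of the RS preset
#'
#' The fixed point of the RS vector field at zero input solves
#' `0.04 v^2 + 5 v + 140 - u = 0` with `u = b v`; the stable root is
#' `v = -70`, `u = -14`.
#' @param n number of neurons
#' @return a `membrane_state` at rest
#' @export
resting_state <- function(n) membrane_state(rep(-70, n), rep(-14, n))

#' Advance membrane dynamics by one grid step
#'
#' The membrane equation is advanced with two half-steps of `dt/2` for
#' numerical stability and the recovery variable once per step.  Neurons at
#' or above the 30 mV threshold on entry are reported as spikes and reset
#' without being advanced; neurons that cross the threshold during the step
#' are reported, reset to `c_reset`, and have `d_jump` added to `u`.  After
#' the step no membrane potential exceeds the threshold.
#'
#' @param state a `membrane_state`
#' @param params a `neuron_params`
#' @param input_current per-neuron input current (recycled if scalar)
#' @param dt grid step (ms), default 1
#' @return `list(state = membrane_state, spikes = integer vector of 1-based
#'   indices of neurons that fired)`
#' @export
step_membrane <- function(state, params, input_current = 0, dt = 1) {
  v <- state$v; u <- state$u
  n <- length(v)
  I <- rep_len(as.numeric(input_current), n)
  if (any(!is.finite(v)) || any(!is.finite(u))) {
    bad <- which(!is.finite(v) | !is.finite(u))
    stop("integration divergence: non-finite state for neuron index ",
         paste(bad, collapse = ", "))
  }
  fired_entry <- v >= IZH_SPIKE_THRESHOLD
  adv <- !fired_entry
  if (any(adv)) {
    for (half in 1:2) {
      dv <- 0.04 * v[adv]^2 + 5 * v[adv] + 140 - u[adv] + I[adv]
      v[adv] <- v[adv] + 0.5 * dt * dv
      # once over threshold the quadratic runs away; freeze at a ceiling so
      # the second half-step cannot overflow
      v[adv] <- pmin(v[adv], 90)
    }
    u[adv] <- u[adv] + dt * params$a * (params$b * v[adv] - u[adv])
  }
  if (any(!is.finite(v)) || any(!is.finite(u))) {
    bad <- which(!is.finite(v) | !is.finite(u))
    stop("integration divergence: non-finite state for neuron index ",
         paste(bad, collapse = ", "))
  }
  fired <- v >= IZH_SPIKE_THRESHOLD
  if (any(fired)) {
    v[fired] <- params$c_reset
    u[fired] <- u[fired] + params$d_jump
  }
  list(state = membrane_state(v, u), spikes = which(fired))
}

#' Receptor conductance state
#'
#' @param n number of neurons
#' @param g_ampa,g_nmda,g_gabaa,g_gabab initial conductances (non-negative)
#' @return an object of class `receptor_state`
#' @export
receptor_state <- function(n, g_ampa = 0, g_nmda = 0, g_gabaa = 0,
                           g_gabab = 0) {
  out <- list(ampa = rep_len(as.numeric(g_ampa), n),
              nmda = rep_len(as.numeric(g_nmda), n),
              gabaa = rep_len(as.numeric(g_gabaa), n),
              gabab = rep_len(as.numeric(g_gabab), n))
  if (any(unlist(out) < 0)) stop("conductances must be non-negative")
  structure(out, class = "receptor_state")
}

#' Synaptic input current from the four receptor conductances
#'
#' The AMPA term has reversal 0 mV; NMDA uses the magnesium-block factor
#' `((-80 - v)/60)^2 / (1 + ((-80 - v)/60)^2)` with reversal 0 mV; GABA_A
#' and GABA_B reverse at -70 and -90 mV.
#'
#' @param receptors a `receptor_state`
#' @param v per-neuron membrane potential (mV)
#' @return per-neuron input current
#' @export
synaptic_current <- function(receptors, v) {
  mg <- ((-80 - v) / 60)^2
  receptors$ampa * (0 - v) +
    receptors$nmda * (mg / (1 + mg)) * (0 - v) +
    receptors$gabaa * (-70 - v) +
    receptors$gabab * (-90 - v)
}

#' Decay receptor conductances and apply spike arrivals
#'
#' Each conductance first decays by its exponential factor
#' `exp(-dt / tau)` and then accumulates the summed weights of the arrivals
#' routed to its receptor.
#'
#' @param receptors a `receptor_state`
#' @param arrivals `NULL`, or a data.frame with columns `neuron` (1-based),
#'   `receptor` (one of `"ampa"`, `"nmda"`, `"gabaa"`, `"gabab"`) and
#'   `weight` (non-negative)
#' @param dt grid step (ms)
#' @return the updated `receptor_state`
#' @export
step_conductances <- function(receptors, arrivals = NULL, dt = 1) {
  for (r in names(RECEPTOR_TAU)) {
    receptors[[r]] <- receptors[[r]] * exp(-dt / RECEPTOR_TAU[[r]])
  }
  if (!is.null(arrivals) && nrow(arrivals) > 0) {
    if (any(arrivals$weight < 0)) {
      stop("contract violation: negative weight delivery")
    }
    for (i in seq_len(nrow(arrivals))) {
      r <- arrivals$receptor[i]
      k <- arrivals$neuron[i]
      receptors[[r]][k] <- receptors[[r]][k] + arrivals$weight[i]
    }
  }
  receptors
}

#' Delayed spike buffer
#'
#' Queue of pending synaptic deliveries keyed by arrival step.  A spike
#' emitted at step `t` on a synapse with delay `D` is delivered at exactly
#' step `t + D`.
#'
#' @param max_delay largest delay the buffer must hold (ms)
#' @return an object of class `spike_buffer`
#' @export
spike_buffer <- function(max_delay) {
  e <- new.env(parent = emptyenv())
  e$slots <- vector("list", max_delay + 1)
  e$max_delay <- max_delay
  structure(e, class = "spike_buffer")
}

#' Enqueue a delivery
#' @param buf a `spike_buffer`
#' @param emit_step step at which the spike was emitted
#' @param delay axonal delay in steps (0 < delay <= max_delay)
#' @param delivery a list/row carrying target neuron, receptor and weight
#' @export
buffer_push <- function(buf, emit_step, delay, delivery) {
  stopifnot(delay >= 1, delay <= buf$max_delay + 1)
  slot <- (emit_step + delay) %% (buf$max_delay + 1) + 1
  buf$slots[[slot]] <- c(buf$slots[[slot]], list(delivery))
  invisible(buf)
}

#' Pop all deliveries due at a step
#' @param buf a `spike_buffer`
#' @param step current step
#' @return list of deliveries due now (possibly empty)
#' @export
buffer_pop <- function(buf, step) {
  slot <- step %% (buf$max_delay + 1) + 1
  due <- buf$slots[[slot]]
  buf$slots[slot] <- list(NULL)
  if (is.null(due)) list() else due
}
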