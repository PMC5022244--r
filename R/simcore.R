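# Fixed-point weight arithmetic -----------------------------------------
#
# Ring-buffer accumulators mirror the hardware's saturating integer
# arithmetic. Encoded weights are stored as integer-valued doubles (exact up
# to 2^53, far beyond the +/- (2^31 - 1) saturation bound), so accumulation
# is exact integer addition and therefore independent of insertion order --
# the property that makes partition invariance bit-exact rather than
# tolerance-based.

FP_SAT <- 2^31 - 1

#' Encode / decode fixed-point synaptic weights
#'
#' @param w Weight(s) in real units.
#' @param x Encoded weight(s).
#' @param fraction_bits Number of fraction bits (default 16).
#' @return `fp_encode` returns integer-valued doubles; `fp_decode` returns
#'   real weights.
#' @export
fp_encode <- function(w, fraction_bits = 16) {
  x <- round(w * 2^fraction_bits)
  pmax(pmin(x, FP_SAT), -FP_SAT)
}

#' @rdname fp_encode
#' @export
fp_decode <- function(x, fraction_bits = 16) {
  x / 2^fraction_bits
}

fp_saturate <- function(x) pmax(pmin(x, FP_SAT), -FP_SAT)

# Ring buffer ------------------------------------------------------------

#' Create a delay ring buffer
#'
#' A circular, delay-indexed accumulator: weights inserted with delay `d`
#' remain in slot `d` steps ahead of the read pointer until drained into the
#' neurons' input. Accumulation is saturating fixed-point addition.
#'
#' A weight inserted with `delay = d` during step `s` (i.e. after step `s`'s
#' drain) is returned by the drain of step `s + d`; the minimum delay is one
#' step.
#'
#' @param n_neurons Number of neurons covered by the buffer.
#' @param depth Number of delay slots `D` (maximum delay in steps).
#' @param fraction_bits Fixed-point fraction bits.
#' @return An object of class `ring_buffer`.
#' @export
ring_buffer <- function(n_neurons, depth = 16, fraction_bits = 16) {
  structure(
    list(slots = matrix(0, nrow = depth, ncol = n_neurons),
         ptr = 1L, depth = as.integer(depth), n = as.integer(n_neurons),
         fraction_bits = fraction_bits),
    class = "ring_buffer"
  )
}

#' Insert weights into a ring buffer
#'
#' Adds (saturating, fixed-point) each weight to the slot `delay` steps ahead
#' for the given neuron. Arguments are recycled to a common length; repeated
#' (neuron, delay) targets accumulate exactly.
#'
#' @param rb A [ring_buffer()].
#' @param neuron 1-based neuron index (vectorized).
#' @param delay Delay in steps, `1 <= delay <= depth` (vectorized).
#' @param weight Real-valued weight(s); encoded internally.
#' @return The updated ring buffer.
#' @export
ring_insert <- function(rb, neuron, delay, weight) {
  n <- max(length(neuron), length(delay), length(weight))
  neuron <- rep_len(neuron, n); delay <- rep_len(delay, n)
  weight <- rep_len(weight, n)
  if (any(delay < 1 | delay > rb$depth)) {
    stop("delay out of range [1, ", rb$depth, "]")
  }
  slot <- ((rb$ptr - 1L + delay - 1L) %% rb$depth) + 1L
  idx <- (neuron - 1L) * rb$depth + slot
  w <- fp_encode(weight, rb$fraction_bits)
  add <- rowsum(w, idx)
  at <- as.integer(rownames(add))
  rb$slots[at] <- fp_saturate(rb$slots[at] + add[, 1])
  rb
}

#' Drain the current ring-buffer slot
#'
#' Returns the weights accumulated for the current step (converted back to
#' real units), zeroes the slot and advances the read pointer.
#'
#' @param rb A [ring_buffer()].
#' @return `list(input = numeric vector per neuron, buffer = advanced ring)`.
#' @export
ring_drain <- function(rb) {
  out <- fp_decode(rb$slots[rb$ptr, ], rb$fraction_bits)
  rb$slots[rb$ptr, ] <- 0
  rb$ptr <- (rb$ptr %% rb$depth) + 1L
  list(input = out, buffer = rb)
}

# LIF dynamics -----------------------------------------------------------

#' Advance a population of LIF neurons by one time step
#'
#' Exact (per-step closed-form exponential) integration: each receptor
#' current first decays by `exp(-dt/tau_syn)` and receives the drained
#' ring-buffer input; the membrane then relaxes toward
#' `v_rest + R * I` with factor `exp(-dt/tau_m)`, treating the total current
#' as constant within the step. Threshold crossing emits a spike, resets the
#' membrane and starts the refractory counter; refractory neurons are held
#' at `v_reset` while their synaptic currents keep evolving.
#'
#' @param state List with `v` (mV), `refrac` (steps remaining, integer) and
#'   `i_syn` (matrix receptors x neurons); see [init_neuron_state()].
#' @param drained_input Named list (by receptor) of input vectors for this
#'   step, in weight units.
#' @param params A [neuron_params()].
#' @param dt Time step (ms).
#' @param i_extra Optional additional current vector (DC stimuli).
#' @return `list(state = updated state, spiked = logical vector)`.
#' @export
lif_step <- function(state, drained_input, params, dt, i_extra = 0) {
  receptors <- rownames(state$i_syn)
  for (r in receptors) {
    dec <- exp(-dt / params$tau_syn[[r]])
    inp <- drained_input[[r]]
    if (is.null(inp)) inp <- 0
    if (any(!is.finite(inp))) {
      stop("non-finite synaptic input at neuron index ",
           paste(which(!is.finite(inp)), collapse = ", "))
    }
    state$i_syn[r, ] <- state$i_syn[r, ] * dec + inp
  }
  i_total <- .colSums(state$i_syn, nrow(state$i_syn), ncol(state$i_syn)) +
    params$i_offset + i_extra
  v_inf <- params$v_rest + params$r_membrane * i_total
  alpha <- exp(-dt / params$tau_m)

  active <- state$refrac <= 0L
  state$v[active] <- v_inf[active] + (state$v[active] - v_inf[active]) * alpha
  state$v[!active] <- params$v_reset
  state$refrac[!active] <- state$refrac[!active] - 1L

  spiked <- active & state$v >= params$v_thresh
  state$v[spiked] <- params$v_reset
  state$refrac[spiked] <- as.integer(round(params$t_refrac / dt))
  list(state = state, spiked = spiked)
}

#' Initialize LIF state for a population slice
#'
#' @param n Number of neurons.
#' @param params A [neuron_params()].
#' @param v Optional initial voltages (defaults to `v_rest`).
#' @return A state list for [lif_step()].
#' @export
init_neuron_state <- function(n, params, v = NULL) {
  receptors <- names(params$tau_syn)
  list(
    v = if (is.null(v)) rep(params$v_rest, n) else rep_len(v, n),
    refrac = integer(n),
    i_syn = matrix(0, nrow = length(receptors), ncol = n,
                   dimnames = list(receptors, NULL))
  )
}

#' Draw one step of Poisson source spikes
#'
#' Bernoulli approximation of a Poisson process on a grid:
#' `P(spike) = 1 - exp(-rate * dt / 1000)`. Draws from the current global
#' RNG stream; callers seed per-source streams via [stream_seed()].
#'
#' @param rate Source rate (Hz), >= 0 (vectorized).
#' @param dt Time step (ms).
#' @param n Number of independent sources to draw.
#' @return Logical vector of length `n`.
#' @export
poisson_step <- function(rate, dt, n = length(rate)) {
  if (any(rate < 0)) stop("poisson rate must be >= 0")
  stats::runif(n) < -expm1(-rate * dt / 1000)
}
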