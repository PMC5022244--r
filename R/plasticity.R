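#' Pair-based STDP configuration
#'
#' All-pairs trace STDP with additive weight dependence and hard clipping to
#' `[0, w_max]`. A presynaptic spike at time `t` depresses the synapse by
#' `a_minus * s_j(t)` where `s_j` is the postsynaptic trace
#' (`s_j <- s_j * exp(-dt_gap/tau_minus) + 1` at each postsynaptic spike); a
#' postsynaptic spike at `t_j` potentiates by `a_plus * s_i(t_j)` with the
#' analogous presynaptic trace and `tau_plus`. Default magnitudes follow the
#' conventional additive rule (slight depression bias).
#'
#' @param tau_plus,tau_minus Trace time constants (ms), > 0.
#' @param a_plus,a_minus Potentiation / depression amplitudes, >= 0.
#' @param w_max Upper weight bound (> 0); the lower bound is 0.
#' @return An object of class `stdp_config`.
#' @export
stdp_config <- function(tau_plus = 20, tau_minus = 20, a_plus = 0.01,
                        a_minus = 0.012, w_max = 1) {
  stopifnot(tau_plus > 0, tau_minus > 0, a_plus >= 0, a_minus >= 0, w_max > 0)
  structure(
    list(tau_plus = tau_plus, tau_minus = tau_minus,
         a_plus = a_plus, a_minus = a_minus, w_max = w_max, w_min = 0),
    class = "stdp_config"
  )
}

#' Fixed-capacity postsynaptic history queue
#'
#' Per postsynaptic neuron, a time-ordered circular queue of
#' `(spike time, trace value at that time)` entries consumed by deferred
#' plasticity updates. When full, the oldest entry is overwritten and a
#' lost-entry counter incremented (never silently).
#'
#' @param capacity Queue capacity (`Inf` allowed for reference runs).
#' @return An object of class `post_history`.
#' @export
post_history <- function(capacity = 10) {
  structure(list(t = numeric(0), s = numeric(0), capacity = capacity,
                 lost = 0L),
            class = "post_history")
}

#' Record a postsynaptic spike in a history queue
#'
#' Appends `(t, s_j)` with `s_j = s_prev * exp(-(t - t_prev)/tau_minus) + 1`
#' (1 for the first spike). Overflow drops the oldest entry and counts it.
#'
#' @param history A [post_history()].
#' @param t Spike time (ms), >= the last entry's time.
#' @param config An [stdp_config()].
#' @return The updated history.
#' @export
add_post_spike <- function(history, t, config) {
  n <- length(history$t)
  if (n > 0L && t < history$t[n]) {
    stop("postsynaptic spikes must be added in time order")
  }
  s_new <- if (n == 0L) 1 else {
    history$s[n] * exp(-(t - history$t[n]) / config$tau_minus) + 1
  }
  history$t <- c(history$t, t)
  history$s <- c(history$s, s_new)
  if (length(history$t) > history$capacity) {
    drop <- length(history$t) - history$capacity
    history$t <- history$t[-seq_len(drop)]
    history$s <- history$s[-seq_len(drop)]
    history$lost <- history$lost + as.integer(drop)
  }
  history
}

#' Update the presynaptic trace on a presynaptic spike
#'
#' @param s_i Presynaptic trace value stored at the previous spike.
#' @param t Current spike time (ms).
#' @param t_last_spike Previous presynaptic spike time, or `NA` if none.
#' @param config An [stdp_config()].
#' @return The new trace value (`1` for the first spike).
#' @export
add_pre_spike <- function(s_i, t, t_last_spike, config) {
  if (is.na(t_last_spike)) return(1)
  s_i * exp(-(t - t_last_spike) / config$tau_plus) + 1
}

#' Apply the potentiation from one postsynaptic spike
#'
#' Pairs the postsynaptic spike at `t_j` with the presynaptic spike at
#' `t_last_spike` (trace `s_i`): `w' = min(w_max, w + a_plus * s_i *
#' exp(-(t_j - t_last_spike)/tau_plus))`. No-op when no presynaptic spike
#' has occurred yet.
#'
#' @param w Current weight.
#' @param t_j Postsynaptic spike time (ms).
#' @param t_last_spike Last presynaptic spike time, or `NA`.
#' @param s_i Presynaptic trace at `t_last_spike`.
#' @param config An [stdp_config()].
#' @return The updated weight.
#' @export
apply_post_spike <- function(w, t_j, t_last_spike, s_i, config) {
  if (is.na(t_last_spike)) return(w)
  min(config$w_max,
      w + config$a_plus * s_i * exp(-(t_j - t_last_spike) / config$tau_plus))
}

#' Apply the depression from one presynaptic spike
#'
#' Pairs the presynaptic spike at `t` with the most recent postsynaptic
#' history entry `(t_j, s_j)`: `w' = max(0, w - a_minus * s_j *
#' exp(-(t - t_j)/tau_minus))`. No-op when the history is empty.
#'
#' @param w Current weight.
#' @param t Presynaptic spike time (ms).
#' @param t_j Most recent postsynaptic spike time at or before `t`, or `NA`.
#' @param s_j Postsynaptic trace at `t_j`.
#' @param config An [stdp_config()].
#' @return The updated weight.
#' @export
apply_pre_spike <- function(w, t, t_j, s_j, config) {
  if (is.na(t_j)) return(w)
  max(0, w - config$a_minus * s_j * exp(-(t - t_j) / config$tau_minus))
}

#' Create a plastic synaptic row
#'
#' One presynaptic neuron's plastic connections to a processor's
#' postsynaptic slice, together with the row header carrying the deferred
#' state: the last presynaptic spike time, the presynaptic trace at that
#' time, and the time of the last row update.
#'
#' @param post 1-based postsynaptic indices within the slice.
#' @param delay Delays (steps).
#' @param weight Initial weights.
#' @param pre_id Optional global presynaptic id (bookkeeping only).
#' @return An object of class `synaptic_row`.
#' @export
synaptic_row <- function(post, delay = 1, weight = 0, pre_id = NA_integer_) {
  n <- length(post)
  structure(
    list(pre_id = pre_id, post = as.integer(post),
         delay = rep_len(as.integer(delay), n),
         weight = rep_len(weight, n),
         t_last_spike = NA_real_, s_i = 0, t_last_update = -Inf),
    class = "synaptic_row"
  )
}

# Core of the deferred row update. Operates on plain vectors/lists so the
# engine can share it without S3 overhead. `hist_t`/`hist_s` are lists of
# entry-time / trace vectors indexed by the row's (1-based) post ids.
# Returns the updated weights, header fields, the weights to insert and the
# number of history entries replayed (the realized `h` for cost auditing).
process_row_core <- function(t, flush, post, delay, weight,
                             t_last_spike, s_i, t_last_update,
                             hist_t, hist_s, config) {
  if (t < t_last_update) {
    stop("row events must be processed in time order (t < t_last_update)")
  }
  n <- length(post)
  ins_w <- numeric(n)
  replayed <- 0L
  for (k in seq_len(n)) {
    ht <- hist_t[[post[k]]]
    w <- weight[k]
    if (length(ht)) {
      replay <- which(ht > t_last_update & ht <= t)
      replayed <- replayed + length(replay)
      for (j in replay) {
        w <- apply_post_spike(w, ht[j], t_last_spike, s_i, config)
      }
      if (!flush) {
        last <- findInterval(t, ht) # most recent entry at or before t
        if (last > 0L) {
          w <- apply_pre_spike(w, t, ht[last], hist_s[[post[k]]][last], config)
        }
      }
    }
    weight[k] <- w
    ins_w[k] <- w
  }
  if (!flush) {
    s_i <- add_pre_spike(s_i, t, t_last_spike, config)
    t_last_spike <- t
  }
  list(weight = weight, ins_w = if (flush) NULL else ins_w,
       t_last_spike = t_last_spike, s_i = s_i, t_last_update = t,
       replayed = replayed)
}

#' Process a plastic synaptic row (deferred STDP update)
#'
#' Event-driven row update performed when a presynaptic spike (or flush
#' event) reaches a synapse processor. For every synapse in the row, the
#' postsynaptic history entries that accumulated since the last row update
#' are replayed as potentiation; if the event is a real spike (not a flush)
#' the depression against the most recent postsynaptic spike is applied, and
#' the fully updated weight is inserted into the ring buffer at the
#' synapse's delay. The row header is then advanced: a spike updates the
#' presynaptic trace and `t_last_spike`; both spike and flush set
#' `t_last_update`.
#'
#' @param t Event time (ms), >= the row's `t_last_update`.
#' @param flush `TRUE` for a flush event (history replay only).
#' @param row A [synaptic_row()].
#' @param histories List of [post_history()] objects indexed by the row's
#'   1-based post ids.
#' @param ring A [ring_buffer()] covering the slice, or `NULL` to skip
#'   insertion.
#' @param config An [stdp_config()].
#' @return `list(row =, ring =)` with updated weights, header and buffer.
#' @export
process_row <- function(t, flush, row, histories, ring, config) {
  res <- process_row_core(t, flush, row$post, row$delay, row$weight,
                          row$t_last_spike, row$s_i, row$t_last_update,
                          lapply(histories, `[[`, "t"),
                          lapply(histories, `[[`, "s"),
                          config)
  row$weight <- res$weight
  row$t_last_spike <- res$t_last_spike
  row$s_i <- res$s_i
  row$t_last_update <- res$t_last_update
  if (!flush && !is.null(ring) && length(row$post)) {
    ring <- ring_insert(ring, row$post, row$delay, res$ins_w)
  }
  list(row = row, ring = ring)
}

#' Flush policy derived from the network's maximum firing rate
#'
#' A neuron that stays silent for `buffer_size` times the interspike
#' interval equivalent to the network's maximum firing rate risks
#' overflowing the fixed-capacity history queues of its efferent rows; the
#' flush policy makes it emit a flush event at that point, forcing the rows
#' to replay accumulated history. The timer re-arms after each flush.
#'
#' @param max_rate Network-wide maximum firing rate (Hz).
#' @param buffer_size Postsynaptic history capacity.
#' @param dt Time step (ms), used to validate the threshold.
#' @return An object of class `flush_policy` with `threshold_ms`.
#' @export
flush_policy <- function(max_rate, buffer_size = 10, dt = 1) {
  stopifnot(max_rate > 0)
  threshold_ms <- buffer_size * 1000 / max_rate
  if (threshold_ms < dt) stop("flush threshold below one time step")
  structure(list(max_rate = max_rate, buffer_size = buffer_size,
                 threshold_ms = threshold_ms),
            class = "flush_policy")
}

#' Should a neuron emit a flush event?
#'
#' @param t Current time (ms).
#' @param t_last_event Time of the neuron's last spike or flush (ms); use 0
#'   at simulation start.
#' @param policy A [flush_policy()].
#' @return `TRUE` if a flush event should be emitted now.
#' @export
flush_check <- function(t, t_last_event, policy) {
  (t - t_last_event) >= policy$threshold_ms
}
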