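# Independent online all-pairs STDP oracle: the weight update is applied at
# every spike as it happens (no deferral, no history queue). Ties are
# resolved post-before-pre, matching the deferred algorithm's convention
# that history entries at exactly the update time are replayed before the
# presynaptic update.
oracle_stdp <- function(pre_times, post_times, cfg, w0 = 0) {
  ev_t <- c(post_times, pre_times)
  ev_pre <- c(rep(FALSE, length(post_times)), rep(TRUE, length(pre_times)))
  ord <- order(ev_t, ev_pre) # FALSE (post) first at ties
  w <- w0
  s_pre <- 0; t_pre <- NA_real_   # presynaptic trace at its last spike
  s_post <- 0; t_post <- NA_real_ # postsynaptic trace at its last spike
  for (i in ord) {
    t <- ev_t[i]
    if (ev_pre[i]) {
      if (!is.na(t_post)) {
        w <- max(0, w - cfg$a_minus * s_post * exp(-(t - t_post) / cfg$tau_minus))
      }
      s_pre <- if (is.na(t_pre)) 1 else s_pre * exp(-(t - t_pre) / cfg$tau_plus) + 1
      t_pre <- t
    } else {
      if (!is.na(t_pre)) {
        w <- min(cfg$w_max,
                 w + cfg$a_plus * s_pre * exp(-(t - t_pre) / cfg$tau_plus))
      }
      s_post <- if (is.na(t_post)) 1 else
        s_post * exp(-(t - t_post) / cfg$tau_minus) + 1
      t_post <- t
    }
  }
  w
}

# Module-level harness for the deferred algorithm on a single synapse:
# replays the pre/post spike trains through add_post_spike / process_row,
# with optional flush events generated by the presynaptic silence timer.
# A terminal flush at t_end brings the row up to date for comparison.
deferred_stdp <- function(pre_times, post_times, cfg, t_end,
                          capacity = Inf, flush_enabled = FALSE,
                          max_rate = 100, buffer_size = 10, w0 = 0,
                          terminal_flush = TRUE) {
  row <- synaptic_row(post = 1L, delay = 1L, weight = w0)
  hist <- list(post_history(capacity))
  flush_times <- numeric(0)
  if (flush_enabled) {
    pol <- flush_policy(max_rate, buffer_size)
    t_last <- 0
    for (tm in seq_len(t_end)) {
      if (any(pre_times == tm)) {
        t_last <- tm
      } else if (flush_check(tm, t_last, pol)) {
        flush_times <- c(flush_times, tm)
        t_last <- tm
      }
    }
  }
  ev_t <- c(post_times, pre_times, flush_times,
            if (terminal_flush) t_end)
  ev_kind <- c(rep("post", length(post_times)), rep("pre", length(pre_times)),
               rep("flush", length(flush_times)),
               if (terminal_flush) "flush")
  ord <- order(ev_t, ev_kind != "post") # posts first at ties
  lost <- 0L # drops of entries the row had not replayed yet
  for (i in ord) {
    t <- ev_t[i]
    if (ev_kind[i] == "post") {
      h <- hist[[1]]
      if (length(h$t) >= h$capacity && h$t[1] > row$t_last_update) {
        lost <- lost + 1L
      }
      hist[[1]] <- add_post_spike(h, t, cfg)
    } else {
      res <- process_row(t, ev_kind[i] == "flush", row, hist, NULL, cfg)
      row <- res$row
    }
  }
  list(w = row$weight, lost = lost, raw_overflows = hist[[1]]$lost,
       row = row, n_flushes = length(flush_times))
}

# Poisson spike train on a 1 ms grid (distinct integer times).
poisson_train <- function(rate_hz, t_end_ms, seed) {
  set.seed(seed)
  which(stats::runif(t_end_ms) < rate_hz / 1000)
}
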