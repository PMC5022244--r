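# Execution engine: runs a partitioned network step-by-step as a set of
# communicating virtual cores (neuron / synapse / current-input /
# spike-source processors). All randomness (connectivity, source spikes,
# background, initial voltages) is pre-generated from per-stream seeds at
# build time, and ring-buffer accumulation is fixed-point, so the realized
# simulation is bit-identical across any valid partitioning of the same
# network: the central correctness property of the synapse-centric mapping.

#' Build an executable engine from a network and a core allocation
#'
#' Materializes the synaptic matrices, slices them into synapse units
#' according to the allocation (post-synaptically by memory-limit groups,
#' presynaptically by the allocation's processor counts; or column-wise for
#' the standard mapping), pre-generates all stochastic inputs, and wires up
#' the per-step shared input buffers.
#'
#' Event routing emulates multicast keys: a spike emitted at step `t`
#' carries its 0-based global neuron id (plus a flush flag for flush
#' events) and is processed by every synapse unit holding rows for that
#' presynaptic neuron at step `t + 1`; a synaptic delay of `d` steps makes
#' the weight reach the target's input at step `t + d`.
#'
#' @param spec A valid [network_spec()].
#' @param alloc A `core_allocation` from [partition_synapse_centric()] or
#'   [partition_standard()]; defaults to the synapse-centric partition.
#' @param record_v Record membrane traces for all LIF neurons?
#' @return An engine environment; advance it with [engine_step()] or run it
#'   with [run_simulation()].
#' @export
build_engine <- function(spec, alloc = NULL, record_v = FALSE) {
  diags <- validate_network(spec)
  if (length(diags)) {
    stop("invalid network spec:\n  ", paste(diags, collapse = "\n  "))
  }
  if (is.null(alloc)) alloc <- partition_synapse_centric(spec)
  eng <- new.env(parent = emptyenv())
  eng$spec <- spec
  eng$alloc <- alloc
  eng$dt <- spec$dt
  eng$depth <- spec$ring_depth
  eng$fb <- spec$fraction_bits
  eng$n_steps <- as.integer(round(spec$duration / spec$dt))

  # global id layout (0-based), populations in declaration order
  off <- 0L
  eng$pops <- list()
  for (p in spec$populations) {
    eng$pops[[p$name]] <- list(pop = p, offset = off, size = p$size)
    off <- off + p$size
  }
  eng$n_global <- off
  receptors <- unique(unlist(lapply(spec$populations, function(p) {
    if (p$kind == "lif") names(p$params$tau_syn) else character(0)
  })))
  eng$receptors <- receptors
  eng$input_fp <- matrix(0, nrow = eng$n_global, ncol = length(receptors),
                         dimnames = list(NULL, receptors))

  mats <- build_matrices(spec)

  # ---- synapse units ---------------------------------------------------
  eng$syn_units <- list()
  standard <- identical(alloc$mapping, "standard")
  for (pname in names(alloc$detail)) {
    d <- alloc$detail[[pname]]
    pop <- spec$populations[[pname]]
    poff <- eng$pops[[pname]]$offset
    types <- d$types
    if (!length(types)) next
    post_groups_of <- function(t) {
      if (standard) {
        slice_bounds(pop$size, d$n_neuron_cores)
      } else {
        slice_bounds(pop$size, ceiling(pop$size / t$group_post))
      }
    }
    for (t in types) {
      k <- if (standard) 1L else t$k
      prs <- Filter(function(pr) {
        pr$post == pname && pr$receptor == t$receptor &&
          identical(pr$plasticity, t$plasticity)
      }, spec$projections)
      for (g in post_groups_of(t)) {
        for (chunk in seq_len(k)) {
          u <- new.env(parent = emptyenv())
          u$label <- sprintf("%s/%s/post%d-%d/k%d", pname, t$type, g[1], g[2], chunk)
          u$plastic <- t$kind == "stdp"
          u$receptor <- t$receptor
          u$config <- if (u$plastic) spec$plasticity_configs[[t$plasticity]]
          u$g_lo <- poff + g[1] - 1L   # 0-based global post range
          u$g_hi <- poff + g[2] - 1L
          u$n_post <- g[2] - g[1] + 1L
          u$ring <- matrix(0, nrow = eng$depth, ncol = u$n_post)
          u$ptr <- 1L
          u$members <- list()
          w_all <- numeric(0)
          for (pr in prs) {
            preo <- eng$pops[[pr$pre]]$offset
            pre_n <- spec$populations[[pr$pre]]$size
            pbs <- slice_bounds(pre_n, k)
            if (chunk > length(pbs)) next
            pb <- pbs[[chunk]]
            sl <- slice_rows(mats[[pr$name]], post_range = c(g[1] - 1L, g[2] - 1L),
                             pre_range = c(pb[1] - 1L, pb[2] - 1L))
            m <- list(projection = pr$name,
                      pre_glo_lo = preo + pb[1] - 1L,
                      pre_glo_hi = preo + pb[2] - 1L,
                      pre_ptr = sl$pre_ptr,
                      post1 = sl$post + 1L,
                      delay = sl$delay,
                      w_off = length(w_all))
            if (u$plastic) {
              n_pre_chunk <- pb[2] - pb[1] + 1L
              m$t_ls <- rep(NA_real_, n_pre_chunk)
              m$s_i <- numeric(n_pre_chunk)
              m$t_lu <- rep(-Inf, n_pre_chunk)
            } else {
              m$w_fp <- fp_encode(sl$weight, eng$fb)
            }
            w_all <- c(w_all, sl$weight)
            u$members[[length(u$members) + 1L]] <- m
          }
          u$w <- w_all
          if (u$plastic) {
            u$hist_t <- rep(list(numeric(0)), u$n_post)
            u$hist_s <- rep(list(numeric(0)), u$n_post)
            u$last_post_t <- rep(-Inf, u$n_post)
            u$last_post_s <- numeric(u$n_post)
            u$lost <- 0L
            u$capacity <- spec$history_capacity
          }
          u$kind <- t$kind
          u$ev_sum <- 0; u$ev_max <- 0; u$row_sum <- 0; u$row_max <- 0
          u$replay_sum <- 0
          eng$syn_units[[length(eng$syn_units) + 1L]] <- u
        }
      }
    }
  }

  # ---- neuron units ----------------------------------------------------
  eng$neuron_units <- list()
  for (pname in names(alloc$detail)) {
    d <- alloc$detail[[pname]]
    pop <- spec$populations[[pname]]
    poff <- eng$pops[[pname]]$offset
    n_cores <- if (identical(alloc$mapping, "standard")) d$n_neuron_cores
    else ceiling(pop$size / d$nsize)
    v0 <- init_voltages(spec, pop)
    for (b in slice_bounds(pop$size, n_cores)) {
      nu <- new.env(parent = emptyenv())
      nu$label <- sprintf("%s/neurons%d-%d", pname, b[1], b[2])
      nu$pop <- pname
      nu$lo <- b[1]; nu$hi <- b[2]
      nu$g_lo <- poff + b[1] - 1L; nu$g_hi <- poff + b[2] - 1L
      nu$params <- pop$params
      nu$state <- init_neuron_state(b[2] - b[1] + 1L, pop$params,
                                    v = v0[b[1]:b[2]])
      eng$neuron_units[[length(eng$neuron_units) + 1L]] <- nu
    }
  }

  # ---- pre-generated stochastic inputs --------------------------------
  eng$sources <- list()
  eng$background <- list()
  for (p in spec$populations) {
    if (p$kind == "poisson") {
      prob <- -expm1(-p$rate * spec$dt / 1000)
      eng$sources[[p$name]] <- with_stream(
        spec$seed, "source", p$name,
        expr = matrix(stats::runif(p$size * eng$n_steps) < prob,
                      nrow = p$size, ncol = eng$n_steps))
    } else if (!is.null(p$background)) {
      bg <- p$background
      prob <- -expm1(-bg$rate * spec$dt / 1000)
      eng$background[[p$name]] <- list(
        counts = with_stream(
          spec$seed, "background", p$name,
          expr = matrix(stats::rbinom(p$size * eng$n_steps,
                                      bg$n_sources_per_neuron, prob),
                        nrow = p$size, ncol = eng$n_steps)),
        w_fp = fp_encode(bg$weight, eng$fb),
        receptor = bg$receptor)
    }
  }

  # ---- flush bookkeeping ----------------------------------------------
  plastic_pre_pops <- unique(vapply(
    Filter(function(pr) !is.null(pr$plasticity), spec$projections),
    function(pr) pr$pre, character(1)))
  eng$flush_enabled <- isTRUE(spec$flush) && length(plastic_pre_pops) > 0
  eng$policy <- flush_policy(spec$max_rate, spec$history_capacity, spec$dt)
  eng$t_last_event <- lapply(eng$pops[plastic_pre_pops],
                             function(p) numeric(p$size))
  eng$flush_count <- 0L

  eng$queue_spikes <- integer(0)
  eng$queue_flush <- integer(0)
  eng$raster_t <- vector("list", eng$n_steps)
  eng$raster_id <- vector("list", eng$n_steps)
  eng$record_v <- record_v
  if (record_v) eng$v_trace <- matrix(NA_real_, eng$n_global, eng$n_steps)
  eng$t <- 0L
  eng
}

init_voltages <- function(spec, pop) {
  vi <- pop$v_init
  if (is.null(vi)) return(rep(pop$params$v_rest, pop$size))
  if (is.list(vi)) {
    with_stream(spec$seed, "vinit", pop$name,
                expr = stats::runif(pop$size, vi$min, vi$max))
  } else {
    rep(vi, pop$size)
  }
}

# DC stimulus vector for one population at time tm (ms).
stim_current <- function(spec, pname, size, tm) {
  st <- spec$stimuli
  out <- 0
  if (is.null(st)) return(out)
  sel <- st$population == pname & st$t_start <= tm & tm < st$t_stop
  if (!any(sel)) return(out)
  out <- numeric(size)
  for (i in which(sel)) {
    out[st$from[i]:st$to[i]] <- out[st$from[i]:st$to[i]] + st$amplitude[i]
  }
  out
}

#' Advance the engine by one time step
#'
#' Executes the per-step dataflow: (1) synapse units process the spike and
#' flush events routed during the previous step (static row insertion or
#' deferred STDP row updates into their ring buffers) in ascending key
#' order; (2) ring buffers are drained and, together with the current-input
#' processors' background vectors, published to the shared input buffers;
#' (3) neuron units sum their inputs per receptor and integrate, and spike
#' sources look up their pre-generated trains; (4) emitted spike and flush
#' keys are enqueued for the next step.
#'
#' @param eng An engine from [build_engine()].
#' @return Invisibly, the 0-based global ids of the neurons that spiked.
#' @export
engine_step <- function(eng) {
  t <- eng$t + 1L
  if (t > eng$n_steps) stop("engine already ran its configured duration")
  dt <- eng$dt
  tm_prev <- (t - 1L) * dt
  depth <- eng$depth

  # --- phase 1: event-driven synaptic processing -----------------------
  sp <- eng$queue_spikes
  fl <- eng$queue_flush
  if (length(sp) || length(fl)) {
    for (u in eng$syn_units) {
      ev_step <- 0L; row_step <- 0L
      if (u$plastic && length(sp)) {
        post_sp <- sp[sp >= u$g_lo & sp <= u$g_hi]
        cfg <- u$config
        min_tlu <- NULL # lazily computed: oldest row update in this unit
        for (g in post_sp) {
          j <- g - u$g_lo + 1L
          ht <- u$hist_t[[j]]
          n <- length(ht)
          s_new <- if (n == 0L) 1 else
            u$hist_s[[j]][n] * exp(-(tm_prev - ht[n]) / cfg$tau_minus) + 1
          if (n >= u$capacity) {
            # overwriting the oldest entry loses information only if some
            # row has not replayed it yet
            if (is.null(min_tlu)) {
              min_tlu <- min(vapply(u$members, function(m) min(m$t_lu),
                                    numeric(1)))
            }
            if (ht[1L] > min_tlu) u$lost <- u$lost + 1L
            u$hist_t[[j]] <- c(ht[-1L], tm_prev)
            u$hist_s[[j]] <- c(u$hist_s[[j]][-1L], s_new)
          } else {
            u$hist_t[[j]] <- c(ht, tm_prev)
            u$hist_s[[j]] <- c(u$hist_s[[j]], s_new)
          }
          u$last_post_t[j] <- tm_prev
          u$last_post_s[j] <- s_new
        }
      }
      for (mi in seq_along(u$members)) {
        m <- u$members[[mi]]
        pres <- sp[sp >= m$pre_glo_lo & sp <= m$pre_glo_hi]
        if (!u$plastic) {
          if (length(pres)) {
            pl <- pres - m$pre_glo_lo + 1L
            starts <- m$pre_ptr[pl] + 1L
            lens <- m$pre_ptr[pl + 1L] - m$pre_ptr[pl]
            nz <- lens > 0L
            if (any(nz)) {
              idx <- sequence(lens[nz], from = starts[nz])
              slot <- (u$ptr - 1L + m$delay[idx] - 1L) %% depth + 1L
              pos <- (m$post1[idx] - 1L) * depth + slot
              add <- rowsum(m$w_fp[idx], pos)
              at <- as.integer(rownames(add))
              u$ring[at] <- fp_saturate(u$ring[at] + add[, 1])
              ev_step <- ev_step + length(idx)
            }
            row_step <- row_step + length(pl)
          }
        } else {
          flp <- fl[fl >= m$pre_glo_lo & fl <= m$pre_glo_hi]
          if (length(pres) || length(flp)) {
            evs <- c(pres, flp)
            isfl <- c(rep(FALSE, length(pres)), rep(TRUE, length(flp)))
            ord <- order(evs)
            cfg <- u$config
            for (q in ord) {
              g <- evs[q]; flush <- isfl[q]
              l <- g - m$pre_glo_lo + 1L
              lo <- m$pre_ptr[l] + 1L; hi <- m$pre_ptr[l + 1L]
              idxr <- if (hi >= lo) lo:hi else integer(0)
              posts <- m$post1[idxr]
              w <- u$w[m$w_off + idxr]
              tlu <- m$t_lu[l]; tls <- m$t_ls[l]; si <- m$s_i[l]
              lt <- u$last_post_t[posts]
              # same per-entry semantics as process_row_core, with the
              # common no-new-history case vectorized: replay potentiation
              # only where entries arrived since the last row update, then
              # depression against each post's most recent entry
              replay <- which(lt > tlu)
              for (k in replay) {
                j <- posts[k]; ht <- u$hist_t[[j]]
                sel <- which(ht > tlu & ht <= tm_prev)
                u$replay_sum <- u$replay_sum + length(sel)
                wk <- w[k]
                for (qq in sel) {
                  wk <- apply_post_spike(wk, ht[qq], tls, si, cfg)
                }
                w[k] <- wk
              }
              if (!flush) {
                has <- which(is.finite(lt))
                if (length(has)) {
                  w[has] <- pmax(0, w[has] - cfg$a_minus *
                                   u$last_post_s[posts[has]] *
                                   exp(-(tm_prev - lt[has]) / cfg$tau_minus))
                }
                si <- add_pre_spike(si, tm_prev, tls, cfg)
                tls <- tm_prev
              }
              if (length(idxr)) u$w[m$w_off + idxr] <- w
              m$t_ls[l] <- tls
              m$s_i[l] <- si
              m$t_lu[l] <- tm_prev
              if (!flush && length(idxr)) {
                slot <- (u$ptr - 1L + m$delay[idxr] - 1L) %% depth + 1L
                pos <- (posts - 1L) * depth + slot
                u$ring[pos] <- fp_saturate(u$ring[pos] +
                                             fp_encode(w, eng$fb))
              }
              ev_step <- ev_step + length(idxr)
              row_step <- row_step + 1L
            }
            u$members[[mi]] <- m
          }
        }
      }
      u$ev_sum <- u$ev_sum + ev_step
      u$ev_max <- max(u$ev_max, ev_step)
      u$row_sum <- u$row_sum + row_step
      u$row_max <- max(u$row_max, row_step)
    }
  }

  # --- phase 2: drain ring buffers + current-input processors ----------
  inp <- eng$input_fp
  inp[] <- 0
  for (u in eng$syn_units) {
    drained <- u$ring[u$ptr, ]
    if (any(drained != 0)) {
      gi <- (u$g_lo:u$g_hi) + 1L
      inp[gi, u$receptor] <- inp[gi, u$receptor] + drained
      u$ring[u$ptr, ] <- 0
    }
    u$ptr <- (u$ptr %% depth) + 1L
  }
  for (pname in names(eng$background)) {
    bg <- eng$background[[pname]]
    po <- eng$pops[[pname]]
    gi <- po$offset + seq_len(po$size)
    inp[gi, bg$receptor] <- inp[gi, bg$receptor] + bg$counts[, t] * bg$w_fp
  }

  # --- phase 3: neuron updates and spike sources -----------------------
  tm <- t * dt
  spikes <- integer(0)
  for (nu in eng$neuron_units) {
    gi <- (nu$g_lo:nu$g_hi) + 1L
    drained <- lapply(rownames(nu$state$i_syn), function(r) {
      fp_decode(inp[gi, r], eng$fb)
    })
    names(drained) <- rownames(nu$state$i_syn)
    i_extra <- stim_current(eng$spec, nu$pop,
                            eng$pops[[nu$pop]]$size, tm)
    if (length(i_extra) > 1) i_extra <- i_extra[nu$lo:nu$hi]
    res <- lif_step(nu$state, drained, nu$params, dt, i_extra)
    nu$state <- res$state
    if (eng$record_v) eng$v_trace[gi, t] <- res$state$v
    if (any(res$spiked)) {
      spikes <- c(spikes, nu$g_lo + which(res$spiked) - 1L)
    }
  }
  for (pname in names(eng$sources)) {
    hit <- which(eng$sources[[pname]][, t])
    if (length(hit)) {
      spikes <- c(spikes, eng$pops[[pname]]$offset + hit - 1L)
    }
  }
  spikes <- sort(spikes)

  # --- phase 4: flush checks and routing -------------------------------
  flushes <- integer(0)
  if (eng$flush_enabled) {
    for (pname in names(eng$t_last_event)) {
      po <- eng$pops[[pname]]
      tl <- eng$t_last_event[[pname]]
      local_sp <- spikes[spikes >= po$offset & spikes < po$offset + po$size] -
        po$offset + 1L
      tl[local_sp] <- tm
      due <- which(tm - tl >= eng$policy$threshold_ms)
      if (length(due)) {
        flushes <- c(flushes, po$offset + due - 1L)
        tl[due] <- tm
        eng$flush_count <- eng$flush_count + length(due)
      }
      eng$t_last_event[[pname]] <- tl
    }
    flushes <- sort(flushes)
  }
  eng$queue_spikes <- spikes
  eng$queue_flush <- flushes
  eng$raster_t[[t]] <- rep(tm, length(spikes))
  eng$raster_id[[t]] <- spikes
  eng$t <- t
  invisible(spikes)
}

#' Run a partitioned network simulation
#'
#' Builds the engine and advances it for the requested duration. The result
#' is deterministic given `(spec, alloc)`: the master seed fixes every
#' random stream and fixed-point accumulation removes any dependence on the
#' partitioning.
#'
#' @param spec A valid [network_spec()].
#' @param alloc Optional `core_allocation`; defaults to the synapse-centric
#'   partition under default cost constants.
#' @param duration Override of `spec$duration` (ms).
#' @param record_v Record membrane traces?
#' @return An object of class `sim_result`: `raster` (data frame `time_ms`,
#'   `neuron` with 0-based global ids), `weights` (final plastic weights as
#'   a data frame `projection`, `pre`, `post`, `weight`), `stats` (per-unit
#'   activity for [audit_allocation()]), `flush_count`, `lost_history`,
#'   `spike_counts` per population, plus the spec/alloc used.
#' @export
run_simulation <- function(spec, alloc = NULL, duration = NULL,
                           record_v = FALSE) {
  if (!is.null(duration)) spec$duration <- duration
  if (is.null(alloc)) alloc <- partition_synapse_centric(spec)
  eng <- build_engine(spec, alloc, record_v = record_v)
  for (t in seq_len(eng$n_steps)) engine_step(eng)
  finish_run(eng)
}

finish_run <- function(eng) {
  rt <- unlist(eng$raster_t, use.names = FALSE)
  rid <- unlist(eng$raster_id, use.names = FALSE)
  raster <- data.frame(
    time_ms = if (is.null(rt)) numeric(0) else rt,
    neuron = if (is.null(rid)) integer(0) else rid
  )
  weights <- extract_weights(eng)
  stats <- do.call(rbind, lapply(eng$syn_units, function(u) {
    n <- max(eng$t, 1L)
    data.frame(core = u$label, role = "synapse", kind = u$kind,
               h = if (u$row_sum > 0) u$replay_sum / u$row_sum else 0,
               n_neurons = u$n_post,
               mean_events = u$ev_sum / n, peak_events = u$ev_max,
               mean_rows = u$row_sum / n, peak_rows = u$row_max)
  }))
  nstats <- do.call(rbind, lapply(eng$neuron_units, function(nu) {
    data.frame(core = nu$label, role = "neuron", kind = "lif", h = 0,
               n_neurons = nu$hi - nu$lo + 1L,
               mean_events = 0, peak_events = 0, mean_rows = 0, peak_rows = 0)
  }))
  stats <- rbind(stats, nstats)
  offs <- vapply(eng$pops, `[[`, integer(1), "offset")
  sizes <- vapply(eng$pops, `[[`, integer(1), "size")
  counts <- vapply(names(eng$pops), function(pn) {
    sum(raster$neuron >= offs[[pn]] & raster$neuron < offs[[pn]] + sizes[[pn]])
  }, numeric(1))
  structure(
    list(raster = raster, weights = weights, stats = stats,
         flush_count = eng$flush_count,
         lost_history = sum(vapply(eng$syn_units, function(u) {
           if (u$plastic) u$lost else 0L
         }, integer(1))),
         spike_counts = counts,
         populations = data.frame(name = names(eng$pops),
                                  offset = unname(offs), size = unname(sizes)),
         duration = eng$t * eng$dt, dt = eng$dt,
         v_trace = if (eng$record_v) eng$v_trace,
         mapping = eng$alloc$mapping),
    class = "sim_result"
  )
}

extract_weights <- function(eng) {
  out <- list()
  for (u in eng$syn_units) {
    if (!u$plastic) next
    for (m in u$members) {
      n_entries <- m$pre_ptr[length(m$pre_ptr)]
      if (n_entries == 0) next
      pre0 <- rep(m$pre_glo_lo:m$pre_glo_hi, diff(m$pre_ptr))
      out[[length(out) + 1L]] <- data.frame(
        projection = m$projection,
        pre = pre0,
        post = u$g_lo + m$post1 - 1L,
        weight = u$w[m$w_off + seq_len(n_entries)]
      )
    }
  }
  if (!length(out)) {
    return(data.frame(projection = character(0), pre = integer(0),
                      post = integer(0), weight = numeric(0)))
  }
  w <- do.call(rbind, out)
  w[order(w$projection, w$pre, w$post), , drop = FALSE]
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", x$duration, " ms (dt ", x$dt, " ms), mapping: ",
      x$mapping, "\n", sep = "")
  cat("  spikes:", nrow(x$raster), " flushes:", x$flush_count,
      " lost history entries:", x$lost_history, "\n")
  for (i in seq_len(nrow(x$populations))) {
    p <- x$populations[i, ]
    r <- x$spike_counts[[p$name]] / p$size / (x$duration / 1000)
    cat(sprintf("  %-12s %6d cells, mean rate %.2f Hz\n", p$name, p$size, r))
  }
  invisible(x)
}
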