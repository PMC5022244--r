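#' Clock-cycle cost constants of the processing cores
#'
#' Per-step and per-event cycle costs used by the planning cost models and
#' the feasibility audit. The per-synaptic-event and per-neuron costs come
#' from profiling of the respective processing loops on 200 MHz cores; the
#' per-row overheads (interrupt servicing, DMA setup, loop setup) are not
#' independently published and default to values calibrated against the
#' processor counts the cost model must reproduce (see the methods
#' vignette); both are user-overridable.
#'
#' @param clock Core clock rate (cycles/s).
#' @param std_per_neuron Standard mapping: cycles per neuron per step
#'   (static synapses).
#' @param std_per_event Standard mapping: cycles per static synaptic event.
#' @param std_stdp_per_neuron Standard mapping: cycles per neuron per step
#'   with STDP synapses.
#' @param stdp_event_base,stdp_event_per_h Standard mapping STDP: cycles per
#'   synaptic event `= base + per_h * h`, `h` being the expected number of
#'   postsynaptic history entries replayed per row update.
#' @param sc_static_per_event Synapse-centric: cycles per static event.
#' @param sc_stdp_event_base,sc_stdp_event_per_h Synapse-centric STDP:
#'   cycles per event `= base + per_h * h`.
#' @param sc_static_per_row,sc_stdp_per_row Synapse-centric fixed cost per
#'   row fetch (cycles).
#' @param std_neuron_cap Practical cap on neurons per core under the
#'   standard mapping with static synapses.
#' @param neuron_proc_cap Neurons a dedicated neuron processor can simulate.
#' @param static_post_limit,stdp_post_limit Postsynaptic neurons whose
#'   static / STDP afferents fit one synapse processor (ring-buffer and
#'   history memory limits).
#' @param chip_cores Cores per chip sharing one memory-buffer group.
#' @return An object of class `cost_constants`.
#' @export
cost_constants <- function(clock = 200e6,
                           std_per_neuron = 181,
                           std_per_event = 21,
                           std_stdp_per_neuron = 187,
                           stdp_event_base = 131, stdp_event_per_h = 31,
                           sc_static_per_event = 15,
                           sc_stdp_event_base = 107, sc_stdp_event_per_h = 30,
                           sc_static_per_row = 800, sc_stdp_per_row = 1500,
                           std_neuron_cap = 256, neuron_proc_cap = 1024,
                           static_post_limit = 1024, stdp_post_limit = 512,
                           chip_cores = 16) {
  x <- as.list(environment())
  stopifnot(all(vapply(x, function(v) is.numeric(v) && v > 0, logical(1))))
  structure(x, class = "cost_constants")
}

# Cycles per synaptic event for a given processing kind.
per_event_cycles <- function(kind, h, costs, synapse_centric = TRUE) {
  if (synapse_centric) {
    switch(kind,
           static = costs$sc_static_per_event,
           stdp = costs$sc_stdp_event_base + costs$sc_stdp_event_per_h * h)
  } else {
    switch(kind,
           static = costs$std_per_event,
           stdp = costs$stdp_event_base + costs$stdp_event_per_h * h)
  }
}

per_row_cycles <- function(kind, costs) {
  switch(kind, static = costs$sc_static_per_row, stdp = costs$sc_stdp_per_row)
}

#' Planning assumptions about network activity
#'
#' @param mean_presynaptic_rate Expected presynaptic firing rate (Hz) used
#'   for cost estimation; defaults to the 3 Hz cortical assumption behind
#'   the 8000 x 3 Hz = 24 kHz per-neuron input figure.
#' @param h Expected postsynaptic history entries replayed per row update
#'   (1 when pre and post fire at approximately the same rate).
#' @param rates Optional named vector of per-population rate overrides (Hz).
#' @return An object of class `rate_assumptions`.
#' @export
rate_assumptions <- function(mean_presynaptic_rate = 3, h = 1, rates = NULL) {
  stopifnot(mean_presynaptic_rate > 0, h >= 0)
  structure(list(mean_presynaptic_rate = mean_presynaptic_rate, h = h,
                 rates = rates),
            class = "rate_assumptions")
}

pop_rate <- function(pop, rates) {
  if (!is.null(rates$rates) && pop$name %in% names(rates$rates)) {
    return(unname(rates$rates[[pop$name]]))
  }
  if (pop$kind == "poisson") pop$rate else rates$mean_presynaptic_rate
}

#' Neurons per core under the standard (column-wise) mapping
#'
#' Evaluates the standard-mapping cost model
#' `floor(clock / (per_neuron/dt + per_event(h) * mu_input))`, i.e. the
#' number of neurons (with their afferent synapse processing) that fit one
#' core within a real-time step. The static estimate is capped at
#' `std_neuron_cap`, the value used in practice.
#'
#' @param dt Time step (ms).
#' @param mu_input Per-neuron synaptic input rate (events/s).
#' @param plastic STDP synapses?
#' @param h Expected history entries per row update.
#' @param costs A [cost_constants()].
#' @return Integer neuron count.
#' @export
estimate_standard_neurons_per_core <- function(dt, mu_input, plastic = FALSE,
                                               h = 1, costs = cost_constants()) {
  stopifnot(dt > 0, mu_input >= 0)
  dts <- dt / 1000
  n <- if (plastic) {
    floor(costs$clock / (costs$std_stdp_per_neuron / dts +
                           per_event_cycles("stdp", h, costs, FALSE) * mu_input))
  } else {
    min(floor(costs$clock / (costs$std_per_neuron / dts +
                               costs$std_per_event * mu_input)),
        costs$std_neuron_cap)
  }
  as.integer(n)
}

#' Synaptic-event throughput of one synapse processor
#'
#' `clock / (per_event + per_row / row_len)` events per second: the row-aware
#' capacity of a synapse processor. With `per_row = 0` this reduces to the
#' peak models `clock/15` (static) and `clock/(107 + 30 h)` (STDP).
#'
#' @param row_len Mean synapses per row (>= 1 unless `per_row = 0`).
#' @param kind `"static"` or `"stdp"`.
#' @param h Expected history entries per row update.
#' @param per_row Per-row overhead override (cycles); `NULL` for the default
#'   constant of `kind`.
#' @param costs A [cost_constants()].
#' @return Events per second.
#' @export
synproc_capacity <- function(row_len = Inf, kind = c("static", "stdp"), h = 1,
                             per_row = NULL, costs = cost_constants()) {
  kind <- match.arg(kind)
  if (is.null(per_row)) per_row <- per_row_cycles(kind, costs)
  pe <- per_event_cycles(kind, h, costs)
  costs$clock / (pe + per_row / row_len)
}

#' Minimal synapse processors for a postsynaptic group
#'
#' Finds the smallest `k` such that, with events and row fetches divided
#' evenly across `k` processors, each stays within its real-time cycle
#' budget: `(events/k) * per_event + (rows_per_s/k) * per_row <= clock`.
#'
#' @param n_post Neurons in the postsynaptic group.
#' @param per_neuron_input Synaptic input rate per neuron (events/s).
#' @param rows_per_s Row fetch rate (presynaptic spikes/s reaching the
#'   group); 0 recovers the peak (row-overhead-free) model.
#' @param row_len Mean row length (synapses); used only for the
#'   single-row feasibility check.
#' @param kind `"static"` or `"stdp"`.
#' @param h Expected history entries per row update.
#' @param per_row Per-row overhead override (cycles).
#' @param dt Time step (ms), for the single-row feasibility check.
#' @param costs A [cost_constants()].
#' @return Integer processor count.
#' @export
count_synapse_processors <- function(n_post, per_neuron_input, rows_per_s = 0,
                                     row_len = NULL, kind = c("static", "stdp"),
                                     h = 1, per_row = NULL, dt = 1,
                                     costs = cost_constants()) {
  kind <- match.arg(kind)
  stopifnot(n_post >= 1, per_neuron_input >= 0, rows_per_s >= 0)
  if (is.null(per_row)) per_row <- per_row_cycles(kind, costs)
  pe <- per_event_cycles(kind, h, costs)
  if (!is.null(row_len) && row_len * pe + per_row > costs$clock * dt / 1000) {
    stop("a single synaptic row of length ", row_len,
         " exceeds the per-step cycle budget: infeasible")
  }
  events <- n_post * per_neuron_input
  k <- ceiling((events * pe + rows_per_s * per_row) / costs$clock)
  as.integer(max(1, k))
}

# Group a population's afferent projections by synapse type, i.e. by
# (receptor, plasticity rule): the first splitting criterion. Returns per
# type the expected event rate per postsynaptic neuron, the row-fetch rate
# and the mean connection probability.
afferent_types <- function(spec, pop, rates) {
  types <- list()
  for (pr in spec$projections) {
    if (pr$post != pop$name) next
    pre <- spec$populations[[pr$pre]]
    key <- paste0(pr$receptor, if (!is.null(pr$plasticity)) paste0("/", pr$plasticity))
    kind <- if (is.null(pr$plasticity)) "static" else "stdp"
    r <- pop_rate(pre, rates)
    p <- if (is.null(pr$p)) nrow(pr$pairs) / (pre$size * pop$size) else pr$p
    t <- types[[key]]
    if (is.null(t)) {
      t <- list(type = key, kind = kind, receptor = pr$receptor,
                plasticity = pr$plasticity, events_per_post = 0,
                rows_per_s = 0, n_pre = 0, p_events = 0)
    }
    t$events_per_post <- t$events_per_post + pre$size * p * r
    t$rows_per_s <- t$rows_per_s + pre$size * r
    t$n_pre <- t$n_pre + pre$size
    t$p_events <- t$p_events + pre$size * p
    types[[key]] <- t
  }
  types
}

#' Partition a network using the synapse-centric mapping
#'
#' Allocates dedicated neuron, synapse and current-input virtual cores.
#' Afferent synapses of each population are split (a) by synapse type
#' (receptor x plasticity rule), so each synapse processor holds one ring
#' buffer and one rule; (b) postsynaptically into groups bounded by the
#' ring-buffer / history memory limits (1024 static, 512 STDP); and (c)
#' presynaptically into the minimal processor count whose cycle budget
#' covers the estimated event and row-fetch load. Neuron processors default
#' to 1024 neurons, halved to 512 when a 1024-neuron group needs four or
#' more synapse processors or the cores sharing one memory-buffer group
#' would exceed a chip; the synapse-core total is scaled accordingly.
#' Populations with background input get one current-input processor per
#' neuron core; Poisson source populations get spike-source cores.
#'
#' @param spec A valid [network_spec()].
#' @param rates A [rate_assumptions()].
#' @param costs A [cost_constants()].
#' @param presyn_split Optional integer forcing the presynaptic split `k`
#'   of every synapse type (used for partition-invariance experiments).
#' @return An object of class `core_allocation`: a `cores` data frame (one
#'   row per virtual core with role, population, type, slice and estimated
#'   cycles/step), `totals` per role, and per-population detail used by the
#'   engine.
#' @export
partition_synapse_centric <- function(spec, rates = rate_assumptions(),
                                      costs = cost_constants(),
                                      presyn_split = NULL) {
  diags <- validate_network(spec)
  if (length(diags)) {
    stop("invalid network spec:\n  ", paste(diags, collapse = "\n  "))
  }
  dts <- spec$dt / 1000
  budget <- costs$clock * dts
  cores <- list()
  detail <- list()
  add_core <- function(role, pop, type, lo, hi, cycles) {
    cores[[length(cores) + 1L]] <<- data.frame(
      role = role, population = pop, type = type,
      slice_start = lo, slice_end = hi, n_items = hi - lo + 1L,
      cycles_per_step = cycles)
  }

  for (pop in spec$populations) {
    if (pop$kind == "poisson") {
      n_src_cores <- ceiling(pop$size / costs$neuron_proc_cap)
      bounds <- slice_bounds(pop$size, n_src_cores)
      for (b in bounds) add_core("spike_source", pop$name, "poisson",
                                 b[1], b[2], 0)
      next
    }
    if (pop$size < 1) stop("empty population '", pop$name, "'")
    types <- afferent_types(spec, pop, rates)

    k_group <- 0          # synapse processors per 1024-neuron post group
    per_type <- list()
    for (t in types) {
      limit <- if (t$kind == "static") costs$static_post_limit else costs$stdp_post_limit
      group_post <- min(pop$size, limit)
      row_len <- max(1e-9, t$p_events * group_post / t$n_pre) # mean synapses/row
      k <- if (!is.null(presyn_split)) {
        as.integer(presyn_split)
      } else {
        count_synapse_processors(group_post, t$events_per_post,
                                 rows_per_s = t$rows_per_s, row_len = row_len,
                                 kind = t$kind, h = rates$h, dt = spec$dt,
                                 costs = costs)
      }
      k1024 <- if (pop$size >= 1024) k * 1024 / group_post else k
      t$group_post <- group_post
      t$k <- k
      t$k1024 <- k1024
      per_type[[t$type]] <- t
      k_group <- k_group + k1024
    }

    nsize <- costs$neuron_proc_cap
    if (length(per_type) &&
        (k_group >= 4 || (1 + k_group) > costs$chip_cores)) {
      nsize <- costs$neuron_proc_cap / 2
    }
    n_ncores <- ceiling(pop$size / nsize)
    neuron_cycles <- min(pop$size, nsize) * costs$std_per_neuron
    if (neuron_cycles > budget) {
      stop("neuron processor over budget for population '", pop$name, "'")
    }
    bounds <- slice_bounds(pop$size, n_ncores)
    for (b in bounds) {
      add_core("neuron", pop$name, "lif", b[1], b[2],
               (b[2] - b[1] + 1) * costs$std_per_neuron)
      if (!is.null(pop$background)) {
        add_core("current_input", pop$name, pop$background$receptor,
                 b[1], b[2], 0)
      }
    }

    # Synapse-core total for the population: scale the per-1024 processor
    # count by the realized neuron-core size, summing types before rounding.
    n_scores <- ceiling(n_ncores * k_group * nsize / 1024)
    if (length(per_type)) {
      exact <- vapply(per_type, function(t) n_ncores * t$k1024 * nsize / 1024,
                      numeric(1))
      counts <- largest_remainder(exact, n_scores)
      for (i in seq_along(per_type)) {
        t <- per_type[[i]]
        if (counts[i] == 0) next
        pe <- per_event_cycles(t$kind, rates$h, costs)
        prc <- per_row_cycles(t$kind, costs)
        ev_share <- pop$size * t$events_per_post / counts[i]
        row_share <- t$rows_per_s * ceiling(pop$size / t$group_post) / counts[i]
        cyc <- (ev_share * pe + row_share * prc) * dts
        gb <- slice_bounds(pop$size, counts[i])
        for (b in gb) add_core("synapse", pop$name, t$type, b[1], b[2], cyc)
      }
    }
    detail[[pop$name]] <- list(nsize = nsize, k_group = k_group,
                               n_neuron_cores = n_ncores,
                               n_synapse_cores = n_scores,
                               types = per_type)
  }

  cores <- if (length(cores)) do.call(rbind, cores) else
    data.frame(role = character(0))
  if (nrow(cores)) cores$id <- seq_len(nrow(cores))
  totals <- list(
    neuron = sum(cores$role == "neuron"),
    synapse = sum(cores$role == "synapse"),
    current_input = sum(cores$role == "current_input"),
    spike_source = sum(cores$role == "spike_source")
  )
  totals$total <- totals$neuron + totals$synapse + totals$current_input +
    totals$spike_source
  structure(list(mapping = "synapse_centric", cores = cores, totals = totals,
                 detail = detail, dt = spec$dt, costs = costs, rates = rates,
                 presyn_split = presyn_split),
            class = "core_allocation")
}

#' Partition a network using the standard (column-wise) mapping
#'
#' Each core simulates a slice of neurons together with all their afferent
#' synapses; the slice size comes from
#' [estimate_standard_neurons_per_core()] under the planning rate
#' assumptions.
#'
#' @inheritParams partition_synapse_centric
#' @return A `core_allocation` (roles `neuron` for the combined
#'   neuron+synapse cores, plus `spike_source`/`current_input` as needed).
#' @export
partition_standard <- function(spec, rates = rate_assumptions(),
                               costs = cost_constants()) {
  diags <- validate_network(spec)
  if (length(diags)) {
    stop("invalid network spec:\n  ", paste(diags, collapse = "\n  "))
  }
  dts <- spec$dt / 1000
  cores <- list()
  detail <- list()
  add_core <- function(role, pop, type, lo, hi, cycles) {
    cores[[length(cores) + 1L]] <<- data.frame(
      role = role, population = pop, type = type,
      slice_start = lo, slice_end = hi, n_items = hi - lo + 1L,
      cycles_per_step = cycles)
  }
  for (pop in spec$populations) {
    if (pop$kind == "poisson") {
      n_src_cores <- ceiling(pop$size / costs$neuron_proc_cap)
      for (b in slice_bounds(pop$size, n_src_cores)) {
        add_core("spike_source", pop$name, "poisson", b[1], b[2], 0)
      }
      next
    }
    types <- afferent_types(spec, pop, rates)
    mu <- sum(vapply(types, `[[`, numeric(1), "events_per_post"))
    plastic <- any(vapply(types, function(t) t$kind == "stdp", logical(1)))
    npc <- estimate_standard_neurons_per_core(spec$dt, mu, plastic, rates$h, costs)
    if (npc < 1) stop("population '", pop$name, "' infeasible under standard mapping")
    n_cores <- ceiling(pop$size / npc)
    pern <- if (plastic) costs$std_stdp_per_neuron else costs$std_per_neuron
    pe <- per_event_cycles(if (plastic) "stdp" else "static", rates$h, costs, FALSE)
    for (b in slice_bounds(pop$size, n_cores)) {
      n <- b[2] - b[1] + 1
      add_core("neuron", pop$name, "standard", b[1], b[2],
               n * pern + n * mu * pe * dts)
      if (!is.null(pop$background)) {
        add_core("current_input", pop$name, pop$background$receptor, b[1], b[2], 0)
      }
    }
    detail[[pop$name]] <- list(nsize = npc, n_neuron_cores = n_cores,
                               types = types)
  }
  cores <- do.call(rbind, cores)
  cores$id <- seq_len(nrow(cores))
  totals <- list(neuron = sum(cores$role == "neuron"),
                 synapse = 0L,
                 current_input = sum(cores$role == "current_input"),
                 spike_source = sum(cores$role == "spike_source"))
  totals$total <- totals$neuron + totals$synapse + totals$current_input +
    totals$spike_source
  structure(list(mapping = "standard", cores = cores, totals = totals,
                 detail = detail, dt = spec$dt, costs = costs, rates = rates),
            class = "core_allocation")
}

#' @export
print.core_allocation <- function(x, ...) {
  cat("<core_allocation> mapping:", x$mapping, "\n")
  cat(sprintf("  cores: %d neuron, %d synapse, %d current-input, %d source (total %d)\n",
              x$totals$neuron, x$totals$synapse, x$totals$current_input,
              x$totals$spike_source, x$totals$total))
  tab <- x$cores
  if (nrow(tab) > 12) {
    print(utils::head(tab, 10), row.names = FALSE)
    cat("  ... ", nrow(tab) - 10, " more cores\n", sep = "")
  } else {
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

# Contiguous 1-based slice bounds splitting n items into k near-even parts.
slice_bounds <- function(n, k) {
  k <- max(1L, min(as.integer(k), as.integer(n)))
  cuts <- floor(seq(0, n, length.out = k + 1L))
  lapply(seq_len(k), function(i) c(cuts[i] + 1L, cuts[i + 1L]))
}

# Integer apportionment: round `exact` shares to integers summing to total.
largest_remainder <- function(exact, total) {
  fl <- floor(exact)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(exact - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Audit a core allocation against recorded activity
#'
#' Converts the per-step synaptic event and row-fetch counts recorded during
#' a simulation (see [run_simulation()]) into clock cycles using the cost
#' constants, and checks every virtual core against its real-time budget of
#' `clock * dt` cycles per step.
#'
#' @param alloc A `core_allocation`.
#' @param activity A data frame with columns `core` (engine unit label),
#'   `role`, `kind`, `h` (mean history entries replayed), `n_neurons`,
#'   `events` and `rows` (per-step matrices summarised as mean and max); the
#'   `stats` element of a [run_simulation()] result has this shape.
#' @param costs A [cost_constants()]; defaults to the allocation's.
#' @return A data frame with estimated mean/peak cycles per step, the
#'   budget, headroom and an `overrun` flag per core.
#' @export
audit_allocation <- function(alloc, activity, costs = alloc$costs) {
  budget <- costs$clock * alloc$dt / 1000
  cyc <- function(role, kind, h, n_neurons, events, rows, std) {
    if (role == "neuron") {
      n_neurons * costs$std_per_neuron
    } else if (role == "current_input" || role == "spike_source") {
      0
    } else {
      pe <- per_event_cycles(kind, h, costs, synapse_centric = !std)
      prc <- if (std) 0 else per_row_cycles(kind, costs)
      nc <- if (std) n_neurons * (if (kind == "stdp") costs$std_stdp_per_neuron
                                  else costs$std_per_neuron) else 0
      events * pe + rows * prc + nc
    }
  }
  std <- identical(alloc$mapping, "standard")
  out <- activity
  out$mean_cycles <- mapply(cyc, activity$role, activity$kind, activity$h,
                            activity$n_neurons, activity$mean_events,
                            activity$mean_rows, MoreArgs = list(std = std))
  out$peak_cycles <- mapply(cyc, activity$role, activity$kind, activity$h,
                            activity$n_neurons, activity$peak_events,
                            activity$peak_rows, MoreArgs = list(std = std))
  out$budget <- budget
  out$headroom <- 1 - out$peak_cycles / budget
  out$overrun <- out$peak_cycles > budget
  out
}
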