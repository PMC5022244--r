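#' Leaky integrate-and-fire neuron parameters
#'
#' Current-based LIF neuron with exponential synapses. The membrane obeys
#' `tau_m dv/dt = v_rest - v + R * I(t)` where `I(t)` is the sum of the
#' per-receptor synaptic currents plus any constant offset; each receptor
#' current decays exponentially with its own `tau_syn` and jumps by the
#' synaptic weight when a spike arrives. With `r_membrane = 1` (the default)
#' synaptic weights are expressed directly in mV of steady-state drive, the
#' convention used by the shipped benchmark networks.
#'
#' @param tau_m Membrane time constant (ms), > 0.
#' @param v_rest Resting potential (mV). May exceed `v_thresh`, in which case
#'   the neuron fires intrinsically (used by self-sustaining benchmarks).
#' @param v_thresh Spike threshold (mV), must exceed `v_reset`.
#' @param v_reset Post-spike reset potential (mV).
#' @param t_refrac Absolute refractory period (ms), >= 0.
#' @param r_membrane Input scaling (membrane resistance; arbitrary units).
#' @param tau_syn Named numeric vector of synaptic time constants (ms), one
#'   per receptor, e.g. `c(exc = 5, inh = 10)`.
#' @param i_offset Constant input current applied every step (same units as
#'   synaptic weights).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 20, v_rest = -65, v_thresh = -50,
                          v_reset = -65, t_refrac = 5, r_membrane = 1,
                          tau_syn = c(exc = 5, inh = 10), i_offset = 0) {
  stopifnot(is.numeric(tau_syn), length(tau_syn) >= 1)
  if (is.null(names(tau_syn)) || any(!nzchar(names(tau_syn)))) {
    stop("tau_syn must be a named vector (one entry per receptor)")
  }
  structure(
    list(tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
         v_reset = v_reset, t_refrac = t_refrac, r_membrane = r_membrane,
         tau_syn = tau_syn, i_offset = i_offset),
    class = "neuron_params"
  )
}

#' Background input delivered through current-input processors
#'
#' Describes independent Poisson background impinging on every neuron of a
#' population. In the synapse-centric mapping this input is not routed as
#' spike events: dedicated current-input processors draw a Poisson spike
#' vector each step, multiply it by the weight and write the result straight
#' into the neurons' input buffers.
#'
#' @param rate Rate of each source (Hz), >= 0.
#' @param n_sources_per_neuron Number of independent sources per neuron.
#' @param weight Synaptic weight per source spike (finite).
#' @param receptor Receptor name the input targets.
#' @return An object of class `background_input`.
#' @export
background_input <- function(rate, n_sources_per_neuron = 1, weight = 0.1,
                             receptor = "exc") {
  structure(
    list(rate = rate, n_sources_per_neuron = n_sources_per_neuron,
         weight = weight, receptor = receptor),
    class = "background_input"
  )
}

#' Define a population of neurons or spike sources
#'
#' @param name Unique identifier within the network.
#' @param size Number of cells, >= 1.
#' @param params A [neuron_params()] object (ignored for Poisson sources).
#' @param kind `"lif"` for model neurons or `"poisson"` for independent
#'   Poisson spike sources routed as ordinary spike events.
#' @param rate Firing rate (Hz) of each source when `kind = "poisson"`.
#' @param background Optional [background_input()] specification.
#' @param v_init Optional initial-voltage spec for LIF populations: either a
#'   single number or `list(dist = "uniform", min =, max =)`; defaults to
#'   `v_rest`.
#' @return An object of class `population`.
#' @export
population <- function(name, size, params = neuron_params(), kind = c("lif", "poisson"),
                       rate = NULL, background = NULL, v_init = NULL) {
  kind <- match.arg(kind)
  structure(
    list(name = name, size = as.integer(size), params = params, kind = kind,
         rate = rate, background = background, v_init = v_init),
    class = "population"
  )
}

#' Define a projection between two populations
#'
#' Connectivity is either probabilistic (each (pre, post) pair included
#' independently with probability `p`, sampled from a stream keyed by
#' (seed, projection name, pre id)) or an explicit pair list. Delays are
#' integer multiples of the simulation step, all modelled as dendritic and
#' applied postsynaptically through the ring buffer; the minimum delay is
#' one step.
#'
#' @param name Unique projection identifier.
#' @param pre,post Names of the pre- and postsynaptic populations.
#' @param p Connection probability in `[0, 1]`; ignored when `pairs` given.
#' @param pairs Optional two-column matrix of 0-based (pre, post) indices.
#' @param weight Constant weight, or `list(dist = "uniform", min =, max =)`.
#' @param delay Constant delay in steps (>= 1), or
#'   `list(dist = "uniform", min =, max =)` sampled on integers.
#' @param receptor Receptor name; must have a `tau_syn` entry on the target.
#' @param plasticity `NULL` for static synapses, otherwise the name of an
#'   STDP configuration registered in the [network_spec()].
#' @param self_connections Allow self-connections when `pre == post`?
#' @return An object of class `projection`.
#' @export
projection <- function(name, pre, post, p = NULL, pairs = NULL, weight = 0.1,
                       delay = 1, receptor = "exc", plasticity = NULL,
                       self_connections = FALSE) {
  structure(
    list(name = name, pre = pre, post = post, p = p, pairs = pairs,
         weight = weight, delay = delay, receptor = receptor,
         plasticity = plasticity, self_connections = self_connections),
    class = "projection"
  )
}

#' Assemble a complete network description
#'
#' @param populations List of [population()] objects.
#' @param projections List of [projection()] objects.
#' @param dt Simulation time step (ms); 1.0 and 0.1 are the conventional
#'   choices but any positive value is accepted.
#' @param duration Simulated time (ms).
#' @param max_rate Network-wide maximum firing rate (Hz) used to derive the
#'   flush threshold for deferred plasticity.
#' @param seed Integer master seed; all randomness derives from it.
#' @param plasticity_configs Named list of [stdp_config()] objects referenced
#'   by projections.
#' @param stimuli Optional data frame of DC stimuli with columns
#'   `population`, `from`, `to` (1-based neuron indices within the
#'   population), `amplitude`, `t_start`, `t_stop` (ms).
#' @param ring_depth Ring-buffer depth in steps (maximum supported delay).
#' @param history_capacity Capacity of each postsynaptic history queue.
#' @param flush Enable flush events for deferred plasticity?
#' @param fraction_bits Fraction bits of the fixed-point ring-buffer
#'   accumulators.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(populations, projections = list(), dt = 1,
                         duration = 1000, max_rate = 100, seed = 1,
                         plasticity_configs = list(), stimuli = NULL,
                         ring_depth = 16, history_capacity = 10,
                         flush = TRUE, fraction_bits = 16) {
  if (inherits(populations, "population")) populations <- list(populations)
  if (inherits(projections, "projection")) projections <- list(projections)
  names(populations) <- vapply(populations, function(p) p$name, character(1))
  if (length(projections)) {
    names(projections) <- vapply(projections, function(p) p$name, character(1))
  }
  structure(
    list(populations = populations, projections = projections, dt = dt,
         duration = duration, max_rate = max_rate, seed = as.integer(seed),
         plasticity_configs = plasticity_configs, stimuli = stimuli,
         ring_depth = as.integer(ring_depth),
         history_capacity = history_capacity, flush = flush,
         fraction_bits = as.integer(fraction_bits)),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> ", length(x$populations), " populations, ",
      length(x$projections), " projections\n", sep = "")
  for (p in x$populations) {
    cat(sprintf("  %-12s %6d %s\n", p$name, p$size, p$kind))
  }
  cat(sprintf("  dt = %g ms, duration = %g ms, seed = %d, max_rate = %g Hz\n",
              x$dt, x$duration, x$seed, x$max_rate))
  invisible(x)
}

#' Validate a network description
#'
#' Checks every structural invariant of the network description and returns
#' diagnostics rather than raising errors, so a user can see all problems at
#' once. An empty character vector means the description is well formed.
#'
#' @param spec A [network_spec()].
#' @return Character vector of diagnostics, each naming the offending
#'   element; empty if the spec is valid.
#' @export
validate_network <- function(spec) {
  diags <- character(0)
  say <- function(...) diags[[length(diags) + 1L]] <<- sprintf(...)

  if (!is.numeric(spec$dt) || spec$dt <= 0) say("dt must be > 0")
  if (spec$max_rate <= 0) say("max_rate must be > 0")

  pop_names <- vapply(spec$populations, function(p) p$name, character(1))
  if (anyDuplicated(pop_names)) {
    say("population names not unique: %s",
        paste(unique(pop_names[duplicated(pop_names)]), collapse = ", "))
  }
  for (p in spec$populations) {
    if (p$size < 1) say("population '%s': size must be >= 1", p$name)
    if (p$kind == "poisson") {
      if (is.null(p$rate) || p$rate < 0) {
        say("population '%s': poisson source needs rate >= 0", p$name)
      }
      next
    }
    np <- p$params
    if (np$tau_m <= 0) say("population '%s': tau_m must be > 0", p$name)
    if (np$v_thresh <= np$v_reset) {
      say("population '%s': v_thresh must exceed v_reset", p$name)
    }
    if (np$t_refrac < 0) say("population '%s': t_refrac must be >= 0", p$name)
    if (any(np$tau_syn <= 0)) say("population '%s': tau_syn must be > 0", p$name)
    bg <- p$background
    if (!is.null(bg)) {
      if (bg$rate < 0) say("population '%s': background rate must be >= 0", p$name)
      if (!is.finite(bg$weight)) say("population '%s': background weight not finite", p$name)
      if (!(bg$receptor %in% names(np$tau_syn))) {
        say("population '%s': background receptor '%s' has no tau_syn", p$name, bg$receptor)
      }
    }
  }

  prj_names <- vapply(spec$projections, function(p) p$name, character(1))
  if (anyDuplicated(prj_names)) {
    say("projection names not unique: %s",
        paste(unique(prj_names[duplicated(prj_names)]), collapse = ", "))
  }
  for (pr in spec$projections) {
    if (!(pr$pre %in% pop_names)) {
      say("projection '%s': unknown presynaptic population '%s'", pr$name, pr$pre)
      next
    }
    if (!(pr$post %in% pop_names)) {
      say("projection '%s': unknown postsynaptic population '%s'", pr$name, pr$post)
      next
    }
    post_pop <- spec$populations[[pr$post]]
    if (post_pop$kind != "lif") {
      say("projection '%s': target '%s' is not a neuron population", pr$name, pr$post)
      next
    }
    if (is.null(pr$pairs)) {
      if (is.null(pr$p) || pr$p < 0 || pr$p > 1) {
        say("projection '%s': connection probability must lie in [0, 1]", pr$name)
      }
    }
    dmin <- if (is.list(pr$delay)) pr$delay$min else pr$delay
    dmax <- if (is.list(pr$delay)) pr$delay$max else pr$delay
    if (dmin < 1) say("projection '%s': delay < 1 step", pr$name)
    if (dmax > spec$ring_depth) {
      say("projection '%s': delay %d exceeds ring-buffer depth %d",
          pr$name, as.integer(dmax), spec$ring_depth)
    }
    if (!(pr$receptor %in% names(post_pop$params$tau_syn))) {
      say("projection '%s': unknown receptor '%s' on population '%s'",
          pr$name, pr$receptor, pr$post)
    }
    if (!is.null(pr$plasticity) &&
        !(pr$plasticity %in% names(spec$plasticity_configs))) {
      say("projection '%s': unknown plasticity config '%s'", pr$name, pr$plasticity)
    }
  }
  diags
}

# Sample one synaptic row: the connections from presynaptic neuron `pre_id`
# (0-based) to the whole postsynaptic population. Always draws the complete
# row so that postsynaptic slicing cannot perturb the sampled pairs.
sample_row <- function(spec, pr, pre_id, n_post) {
  with_stream(spec$seed, pr$name, pre_id, expr = {
    if (is.null(pr$pairs)) {
      keep <- stats::runif(n_post) < pr$p
      if (!pr$self_connections && pr$pre == pr$post) keep[pre_id + 1L] <- FALSE
      post <- which(keep) - 1L
    } else {
      post <- sort(pr$pairs[pr$pairs[, 1] == pre_id, 2])
    }
    n <- length(post)
    w <- if (is.list(pr$weight)) {
      stats::runif(n, pr$weight$min, pr$weight$max)
    } else {
      rep(pr$weight, n)
    }
    d <- if (is.list(pr$delay)) {
      sample.int(pr$delay$max - pr$delay$min + 1L, n, replace = TRUE) +
        pr$delay$min - 1L
    } else {
      rep(as.integer(pr$delay), n)
    }
    list(post = post, weight = w, delay = as.integer(d))
  })
}

#' Materialize the synaptic matrices of a network
#'
#' Samples every projection's connectivity into per-presynaptic-neuron rows,
#' the unit in which synapses are fetched and processed on spike arrival.
#' Sampling is a pure function of `(spec, spec$seed)`: each row draws from a
#' stream keyed by (seed, projection, pre id), so identical specs yield
#' identical matrices and slicing the postsynaptic dimension (see
#' [slice_rows()]) never changes which pairs exist.
#'
#' @param spec A validated [network_spec()].
#' @return An object of class `syn_matrices`: per projection a packed
#'   structure with `pre_ptr` (row start offsets, length `n_pre + 1`),
#'   `post` (0-based postsynaptic indices), `delay` (steps) and `weight`.
#' @export
build_matrices <- function(spec) {
  diags <- validate_network(spec)
  if (length(diags)) {
    stop("invalid network spec:\n  ", paste(diags, collapse = "\n  "))
  }
  out <- list()
  for (pr in spec$projections) {
    n_pre <- spec$populations[[pr$pre]]$size
    n_post <- spec$populations[[pr$post]]$size
    rows <- vector("list", n_pre)
    for (i in seq_len(n_pre)) {
      rows[[i]] <- sample_row(spec, pr, i - 1L, n_post)
    }
    lens <- vapply(rows, function(r) length(r$post), integer(1))
    out[[pr$name]] <- list(
      projection = pr$name, pre_pop = pr$pre, post_pop = pr$post,
      receptor = pr$receptor, plasticity = pr$plasticity,
      n_pre = n_pre, n_post = n_post,
      pre_ptr = c(0L, cumsum(lens)),
      post = unlist(lapply(rows, `[[`, "post"), use.names = FALSE),
      delay = unlist(lapply(rows, `[[`, "delay"), use.names = FALSE),
      weight = unlist(lapply(rows, `[[`, "weight"), use.names = FALSE)
    )
    if (is.null(out[[pr$name]]$post)) {
      out[[pr$name]]$post <- integer(0)
      out[[pr$name]]$delay <- integer(0)
      out[[pr$name]]$weight <- numeric(0)
    }
  }
  structure(out, class = "syn_matrices")
}

#' Extract the rows a synapse processor would hold
#'
#' Restricts a materialized projection to a postsynaptic slice and an
#' optional presynaptic range, i.e. the portion of the synaptic matrix one
#' synapse processor is responsible for.
#'
#' @param mat One element of a [build_matrices()] result.
#' @param post_range Integer vector `c(lo, hi)` of 0-based postsynaptic ids
#'   (inclusive).
#' @param pre_range Optional `c(lo, hi)` of 0-based presynaptic ids.
#' @return A list with the same packed layout as the input, with `post`
#'   re-expressed relative to `post_range[1]`, plus `pre_ids` (0-based global
#'   ids of the retained rows).
#' @export
slice_rows <- function(mat, post_range, pre_range = NULL) {
  if (is.null(pre_range)) pre_range <- c(0L, mat$n_pre - 1L)
  pre_ids <- pre_range[1]:pre_range[2]
  ptr <- 0L
  pre_ptr <- integer(length(pre_ids) + 1L)
  post <- integer(0); delay <- integer(0); weight <- numeric(0)
  keep_idx <- vector("list", length(pre_ids))
  for (k in seq_along(pre_ids)) {
    i <- pre_ids[k]
    lo <- mat$pre_ptr[i + 1L] + 1L
    hi <- mat$pre_ptr[i + 2L]
    sel <- if (hi >= lo) {
      which(mat$post[lo:hi] >= post_range[1] & mat$post[lo:hi] <= post_range[2]) + lo - 1L
    } else {
      integer(0)
    }
    keep_idx[[k]] <- sel
    pre_ptr[k + 1L] <- pre_ptr[k] + length(sel)
  }
  sel <- unlist(keep_idx, use.names = FALSE)
  list(pre_ids = pre_ids, pre_ptr = pre_ptr,
       post = mat$post[sel] - post_range[1],
       delay = mat$delay[sel], weight = mat$weight[sel],
       post_range = post_range)
}
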