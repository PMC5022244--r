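# Reading and writing the human-readable artifacts: the YAML network
# description, plain-text spike rasters and weight triplets, and the
# JSON allocation report. The YAML schema mirrors the constructor
# arguments; a worked example ships in inst/extdata/poisson_benchmark.yaml.

#' Read a network description from YAML
#'
#' The file holds `populations` (name, size, kind, rate, params with
#' `tau_syn` as a receptor map, background, v_init), `projections` (pre,
#' post, p, weight, delay, receptor, plasticity), named `plasticity`
#' configurations, a `simulation` section (dt, duration, max_rate, seed,
#' ring_depth, history_capacity, flush, fraction_bits) and optional
#' `stimuli` entries. Weight and delay accept either a scalar or
#' `{dist: uniform, min:, max:}`.
#'
#' @param path Path to a YAML network description.
#' @return A [network_spec()].
#' @export
read_network_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  pops <- lapply(y$populations, function(p) {
    params <- if (!is.null(p$params)) {
      pa <- p$params
      do.call(neuron_params, c(
        pa[setdiff(names(pa), "tau_syn")],
        list(tau_syn = unlist(pa$tau_syn))
      ))
    } else {
      neuron_params()
    }
    bg <- if (!is.null(p$background)) do.call(background_input, p$background)
    population(p$name, p$size, params = params,
               kind = if (is.null(p$kind)) "lif" else p$kind,
               rate = p$rate, background = bg, v_init = p$v_init)
  })
  prjs <- lapply(y$projections, function(pr) {
    projection(pr$name, pr$pre, pr$post, p = pr$p,
               weight = if (is.null(pr$weight)) 0.1 else pr$weight,
               delay = if (is.null(pr$delay)) 1 else pr$delay,
               receptor = if (is.null(pr$receptor)) "exc" else pr$receptor,
               plasticity = pr$plasticity)
  })
  cfgs <- lapply(y$plasticity, function(cf) do.call(stdp_config, cf))
  sim <- if (is.null(y$simulation)) list() else y$simulation
  stim <- if (!is.null(y$stimuli)) {
    do.call(rbind, lapply(y$stimuli, as.data.frame))
  }
  do.call(network_spec, c(
    list(populations = pops, projections = prjs,
         plasticity_configs = cfgs, stimuli = stim),
    sim
  ))
}

#' Write a network description to YAML
#'
#' @param spec A [network_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_yaml <- function(spec, path) {
  strip <- function(x) x[!vapply(x, is.null, logical(1))]
  y <- list(
    populations = lapply(unname(spec$populations), function(p) {
      strip(list(name = p$name, size = p$size, kind = p$kind, rate = p$rate,
                 params = if (p$kind == "lif") {
                   pa <- unclass(p$params)
                   pa$tau_syn <- as.list(pa$tau_syn)
                   pa
                 },
                 background = if (!is.null(p$background)) unclass(p$background),
                 v_init = p$v_init))
    }),
    projections = lapply(unname(spec$projections), function(pr) {
      strip(list(name = pr$name, pre = pr$pre, post = pr$post, p = pr$p,
                 weight = pr$weight, delay = pr$delay, receptor = pr$receptor,
                 plasticity = pr$plasticity))
    }),
    plasticity = lapply(spec$plasticity_configs, function(cf) {
      unclass(cf)[c("tau_plus", "tau_minus", "a_plus", "a_minus", "w_max")]
    }),
    simulation = list(dt = spec$dt, duration = spec$duration,
                      max_rate = spec$max_rate, seed = spec$seed,
                      ring_depth = spec$ring_depth,
                      history_capacity = spec$history_capacity,
                      flush = spec$flush, fraction_bits = spec$fraction_bits),
    stimuli = if (!is.null(spec$stimuli)) {
      lapply(seq_len(nrow(spec$stimuli)), function(i) as.list(spec$stimuli[i, ]))
    }
  )
  yaml::write_yaml(strip(y), path)
  invisible(path)
}

#' Write a spike raster as plain text
#'
#' Two columns, `time_ms neuron_global_id`, one line per spike, preceded by
#' a header comment naming the run configuration and seed.
#'
#' @param result A [run_simulation()] result.
#' @param path Output path.
#' @param label Run label for the header.
#' @param seed Seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_raster <- function(result, path, label = "run", seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s mapping=%s dt=%g seed=%s", label, result$mapping,
                     result$dt, seed), con)
  writeLines("# time_ms neuron_global_id", con)
  utils::write.table(result$raster, con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain-text spike raster
#'
#' @param path Path written by [write_raster()].
#' @return Data frame with `time_ms` and `neuron`.
#' @export
read_raster <- function(path) {
  utils::read.table(path, comment.char = "#",
                    col.names = c("time_ms", "neuron"))
}

#' Write plastic weights as plain-text triplets
#'
#' One `pre post weight` line per synapse, grouped by projection (named in
#' comment lines).
#'
#' @param weights The `weights` data frame of a [run_simulation()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pre post weight", con)
  for (pj in unique(weights$projection)) {
    writeLines(sprintf("# projection %s", pj), con)
    utils::write.table(weights[weights$projection == pj,
                               c("pre", "post", "weight")],
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a core-allocation report as JSON
#'
#' Structured report listing every virtual core with its role, population,
#' slice and estimated cycles per step, plus per-role totals.
#'
#' @param alloc A `core_allocation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allocation_json <- function(alloc, path) {
  jsonlite::write_json(
    list(mapping = alloc$mapping, dt_ms = alloc$dt,
         totals = alloc$totals, cores = alloc$cores),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
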