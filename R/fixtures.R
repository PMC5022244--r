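# Programmatic generators for the benchmark networks used throughout the
# package: the Poisson-input synapse-processor benchmark, the Vogels-Abbott
# self-sustaining random network, and a modular attractor skeleton with
# heterogeneous plastic synapse types.

#' DC current for a target LIF firing rate
#'
#' Inverts the closed-form constant-input firing rate of the LIF neuron,
#' `ISI = t_refrac + tau_m * log((v_inf - v_reset)/(v_inf - v_thresh))` with
#' `v_inf = v_rest + R * I`, to find the drive producing a requested rate.
#'
#' @param rate Target rate (Hz); 0 returns 0 drive.
#' @param params A [neuron_params()].
#' @return DC current in weight units.
#' @export
dc_for_rate <- function(rate, params = neuron_params()) {
  if (rate <= 0) return(0)
  isi <- 1000 / rate
  if (isi <= params$t_refrac) {
    stop("requested rate exceeds 1/t_refrac")
  }
  e <- exp((isi - params$t_refrac) / params$tau_m)
  v_inf <- (params$v_thresh * e - params$v_reset) / (e - 1)
  (v_inf - params$v_rest) / params$r_membrane
}

#' Poisson-input synapse-processor benchmark
#'
#' A population of LIF neurons, each receiving a configured aggregate
#' synaptic input rate from many independent low-rate Poisson sources
#' connected with a given probability: the workload used to characterize
#' synaptic processing throughput. The number of sources is
#' `ceiling(mu_input / (source_rate * connectivity))` so each neuron's
#' expected input rate equals `mu_input`. Optionally the projection is
#' plastic, and a DC drive calibrated with [dc_for_rate()] gives the target
#' postsynaptic rate.
#'
#' @param n_post Number of postsynaptic neurons.
#' @param connectivity Connection probability in (0, 1].
#' @param mu_input Aggregate input rate per neuron (events/s).
#' @param source_rate Rate of each Poisson source (Hz).
#' @param weight Synaptic weight (kept small by default so the input does
#'   not itself drive the neurons).
#' @param plastic Use STDP synapses?
#' @param stdp An [stdp_config()] for the plastic variant.
#' @param post_rate Target postsynaptic rate (Hz) produced by DC drive.
#' @param duration,dt,seed Simulation parameters.
#' @param max_rate Network maximum rate for the flush policy.
#' @return A [network_spec()].
#' @export
make_poisson_benchmark <- function(n_post = 1024, connectivity = 1.0,
                                   mu_input = 24000, source_rate = 10,
                                   weight = 0.001, plastic = FALSE,
                                   stdp = stdp_config(w_max = 0.01),
                                   post_rate = 0, duration = 1000, dt = 1,
                                   seed = 1234, max_rate = 100) {
  stopifnot(connectivity > 0, connectivity <= 1, mu_input >= 0)
  params <- neuron_params(tau_m = 20, v_rest = -65, v_thresh = -50,
                          v_reset = -65, t_refrac = 5,
                          tau_syn = c(exc = 5),
                          i_offset = dc_for_rate(post_rate,
                                                 neuron_params(tau_m = 20,
                                                               v_rest = -65,
                                                               v_thresh = -50,
                                                               v_reset = -65,
                                                               t_refrac = 5)))
  pops <- list(population("post", n_post, params))
  prjs <- list()
  cfgs <- list()
  if (mu_input > 0) {
    n_sources <- ceiling(mu_input / (source_rate * connectivity))
    pops <- c(pops, list(population("sources", n_sources, kind = "poisson",
                                    rate = source_rate)))
    prjs <- list(projection("input", "sources", "post", p = connectivity,
                            weight = weight, delay = 1, receptor = "exc",
                            plasticity = if (plastic) "stdp"))
    if (plastic) cfgs <- list(stdp = stdp)
  }
  network_spec(pops, prjs, dt = dt, duration = duration, max_rate = max_rate,
               seed = seed, plasticity_configs = cfgs)
}

#' Vogels-Abbott self-sustaining random network
#'
#' The widely used current-based LIF benchmark: an 80/20
#' excitatory/inhibitory split, all four projections random at probability
#' `p`, with sparse long-range-cortex-like connectivity. Neuron and weight
#' parameters follow the published current-based variant of the benchmark
#' (membrane 20 ms, exc/inh synapses 5/10 ms, threshold -50 mV, reset
#' -60 mV, rest -49 mV, 5 ms refractory); since that reference network has
#' 4000 cells at 2% connectivity, weights are scaled inversely with the
#' expected in-degree so the mean synaptic drive is preserved at other
#' scales. A DC stimulus to the excitatory population during the first
#' `stim_ms` kicks the network into its self-sustained state.
#'
#' @param n_total Total neurons (divisible 80/20).
#' @param p Connection probability.
#' @param dt Time step (ms).
#' @param duration Simulated time (ms).
#' @param seed Master seed.
#' @param stim_ms Duration of the initial DC kick (ms).
#' @return A [network_spec()].
#' @export
make_vogels_abbott <- function(n_total = 10000, p = 0.02, dt = 1,
                               duration = 500, seed = 1, stim_ms = 50) {
  stopifnot(n_total %% 5 == 0)
  n_exc <- as.integer(0.8 * n_total)
  n_inh <- n_total - n_exc
  params <- neuron_params(tau_m = 20, v_rest = -49, v_thresh = -50,
                          v_reset = -60, t_refrac = 5,
                          tau_syn = c(exc = 5, inh = 10))
  # reference scale: 3200 exc / 800 inh at p = 0.02 with w_e = 1.62 mV,
  # w_i = -9 mV; keep expected drive (in-degree x weight) constant
  w_e <- 1.62 * (3200 * 0.02) / (n_exc * p)
  w_i <- -9 * (800 * 0.02) / (n_inh * p)
  vinit <- list(dist = "uniform", min = -60, max = -50)
  pops <- list(
    population("exc", n_exc, params, v_init = vinit),
    population("inh", n_inh, params, v_init = vinit)
  )
  prjs <- list(
    projection("ee", "exc", "exc", p = p, weight = w_e, delay = 1, receptor = "exc"),
    projection("ei", "exc", "inh", p = p, weight = w_e, delay = 1, receptor = "exc"),
    projection("ie", "inh", "exc", p = p, weight = w_i, delay = 1, receptor = "inh"),
    projection("ii", "inh", "inh", p = p, weight = w_i, delay = 1, receptor = "inh")
  )
  stim <- if (stim_ms > 0) {
    data.frame(population = "exc", from = 1L, to = n_exc, amplitude = 1.5,
               t_start = 0, t_stop = stim_ms)
  }
  network_spec(pops, prjs, dt = dt, duration = duration, max_rate = 200,
               seed = seed, stimuli = stim)
}

#' Modular attractor network skeleton
#'
#' A grid of cortical hypercolumns, each holding 1000 excitatory cells
#' evenly divided between 10 competing minicolumns plus 250 shared
#' inhibitory cells. Excitatory-excitatory connectivity carries two plastic
#' synapse types with distinct learning rules trained simultaneously — an
#' AMPA-like rule with a short symmetric coincidence window that sharpens
#' activity within a minicolumn, and an NMDA-like rule with a long
#' asymmetric window that learns sequence transitions — alongside static
#' excitatory drive onto the inhibitory pool and static GABA feedback.
#' Pair it with [attractor_training_stimulus()] to train a repeating
#' temporal sequence of minicolumn activations.
#'
#' @param n_hypercolumns Number of hypercolumns (>= 1).
#' @param p_ee,p_ei,p_ie Connection probabilities (exc-exc plastic types,
#'   exc-inh and inh-exc static).
#' @param duration,dt,seed Simulation parameters.
#' @param max_rate Network maximum rate for the flush policy (Hz).
#' @return A [network_spec()] with populations `exc` (minicolumn-major
#'   order: cells `(m-1)*100 + 1 ... m*100` form minicolumn `m`) and `inh`.
#' @export
make_modular_attractor <- function(n_hypercolumns = 1, p_ee = 0.2,
                                   p_ei = 0.1, p_ie = 0.1, duration = 1000,
                                   dt = 1, seed = 7, max_rate = 100) {
  stopifnot(n_hypercolumns >= 1)
  n_exc <- as.integer(1000 * n_hypercolumns)
  n_inh <- as.integer(250 * n_hypercolumns)
  params_e <- neuron_params(tau_m = 20, v_rest = -70, v_thresh = -55,
                            v_reset = -70, t_refrac = 2,
                            tau_syn = c(ampa = 5, nmda = 150, gaba = 10))
  params_i <- neuron_params(tau_m = 10, v_rest = -70, v_thresh = -55,
                            v_reset = -70, t_refrac = 1,
                            tau_syn = c(ampa = 5, gaba = 10))
  cfgs <- list(
    ampa_rule = stdp_config(tau_plus = 10, tau_minus = 10,
                            a_plus = 0.002, a_minus = 0.002, w_max = 0.2),
    nmda_rule = stdp_config(tau_plus = 100, tau_minus = 100,
                            a_plus = 0.002, a_minus = 0.0005, w_max = 0.2)
  )
  pops <- list(
    population("exc", n_exc, params_e),
    population("inh", n_inh, params_i)
  )
  prjs <- list(
    projection("ee_ampa", "exc", "exc", p = p_ee, weight = 0, delay = 1,
               receptor = "ampa", plasticity = "ampa_rule"),
    projection("ee_nmda", "exc", "exc", p = p_ee, weight = 0, delay = 1,
               receptor = "nmda", plasticity = "nmda_rule"),
    projection("ei", "exc", "inh", p = p_ei, weight = 0.6, delay = 1,
               receptor = "ampa"),
    projection("ie", "inh", "exc", p = p_ie, weight = -1.2, delay = 1,
               receptor = "gaba")
  )
  network_spec(pops, prjs, dt = dt, duration = duration, max_rate = max_rate,
               seed = seed, plasticity_configs = cfgs)
}

#' Sequential minicolumn training stimulus
#'
#' Builds a DC stimulus schedule that activates each hypercolumn's
#' minicolumns in a repeating temporal sequence — the training regime for
#' the attractor's sequence-learning synapses.
#'
#' @param spec A [make_modular_attractor()] network.
#' @param sequence Minicolumn order (1-based indices within a hypercolumn).
#' @param epoch_ms Activation duration per minicolumn (ms).
#' @param n_repeats Number of sequence repetitions.
#' @param amplitude DC amplitude driving the active minicolumn.
#' @param t_start Start time of training (ms).
#' @return The spec with the stimulus schedule attached.
#' @export
attractor_training_stimulus <- function(spec, sequence = 1:10, epoch_ms = 50,
                                        n_repeats = 2, amplitude = 30,
                                        t_start = 0) {
  n_exc <- spec$populations[["exc"]]$size
  n_hyper <- n_exc / 1000
  rows <- list()
  tm <- t_start
  for (rep in seq_len(n_repeats)) {
    for (m in sequence) {
      for (hc in seq_len(n_hyper)) {
        base <- (hc - 1) * 1000 + (m - 1) * 100
        rows[[length(rows) + 1L]] <- data.frame(
          population = "exc", from = base + 1L, to = base + 100L,
          amplitude = amplitude, t_start = tm, t_stop = tm + epoch_ms)
      }
      tm <- tm + epoch_ms
    }
  }
  spec$stimuli <- rbind(spec$stimuli, do.call(rbind, rows))
  if (spec$duration < tm) spec$duration <- tm
  spec
}
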