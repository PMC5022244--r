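# Small reusable test networks.

# one Poisson source feeding one quiet LIF neuron
quiet_pair_spec <- function(delay = 3, duration = 100, rate = 30,
                            weight = 1, seed = 5) {
  p <- neuron_params(tau_m = 20, v_rest = -65, v_thresh = -50, v_reset = -65,
                     t_refrac = 5, tau_syn = c(exc = 5))
  network_spec(
    list(population("post", 1, p),
         population("src", 1, kind = "poisson", rate = rate)),
    list(projection("in", "src", "post", p = 1, weight = weight,
                    delay = delay)),
    duration = duration, seed = seed
  )
}

# self-sustaining recurrent network with mixed plastic/static projections
# and a spread of delays; n is total size at an 80/20 exc/inh split
recurrent_spec <- function(n = 500, duration = 150, seed = 11) {
  params <- neuron_params(tau_m = 20, v_rest = -49, v_thresh = -50,
                          v_reset = -60, t_refrac = 5,
                          tau_syn = c(exc = 5, inh = 10))
  vinit <- list(dist = "uniform", min = -60, max = -50)
  n_exc <- round(0.8 * n)
  network_spec(
    list(population("exc", n_exc, params, v_init = vinit),
         population("inh", n - n_exc, params, v_init = vinit)),
    list(projection("ee", "exc", "exc", p = 0.05, weight = 0.2,
                    delay = list(dist = "uniform", min = 1, max = 8),
                    receptor = "exc", plasticity = "rule"),
         projection("ei", "exc", "inh", p = 0.05, weight = 0.4,
                    delay = list(dist = "uniform", min = 1, max = 8),
                    receptor = "exc"),
         projection("ie", "inh", "exc", p = 0.05, weight = -1.8, delay = 1,
                    receptor = "inh"),
         projection("ii", "inh", "inh", p = 0.05, weight = -1.8, delay = 1,
                    receptor = "inh")),
    dt = 1, duration = duration, max_rate = 200, seed = seed,
    plasticity_configs = list(rule = stdp_config(w_max = 0.4))
  )
}
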