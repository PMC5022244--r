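# Poisson-input synapse-processor benchmark, scaled down for illustration:
# 64 LIF neurons each receiving an expected 2.4 kHz of synaptic input from
# 240 independent 10 Hz Poisson sources (full connectivity).
populations:
- name: post
  size: 64
  kind: lif
  params:
    tau_m: 20.0
    v_rest: -65.0
    v_thresh: -50.0
    v_reset: -65.0
    t_refrac: 5.0
    r_membrane: 1.0
    i_offset: 0.0
    tau_syn:
      exc: 5.0
- name: sources
  size: 240
  kind: poisson
  rate: 10.0
projections:
- name: input
  pre: sources
  post: post
  p: 1.0
  weight: 0.001
  delay: 1
  receptor: exc
  plasticity: stdp
plasticity:
  stdp:
    tau_plus: 20.0
    tau_minus: 20.0
    a_plus: 0.01
    a_minus: 0.012
    w_max: 0.01
simulation:
  dt: 1.0
  duration: 1000.0
  max_rate: 100.0
  seed: 1234
  ring_depth: 16
  history_capacity: 10
  flush: true
  fraction_bits: 16
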