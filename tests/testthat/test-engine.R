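test_that("a silent network stays silent and a zero-duration run is empty", {
  p <- neuron_params(tau_syn = c(exc = 5))
  spec <- network_spec(list(population("a", 20, p)), duration = 50)
  r <- run_simulation(spec)
  expect_equal(nrow(r$raster), 0)
  expect_equal(r$spike_counts[["a"]], 0)

  r0 <- run_simulation(quiet_pair_spec(), duration = 0)
  expect_equal(nrow(r0$raster), 0)
})

test_that("a spike with delay d reaches its target exactly d steps later", {
  for (d in c(1, 3, 7)) {
    spec <- quiet_pair_spec(delay = d)
    r <- run_simulation(spec, record_v = TRUE)
    src_t <- r$raster$time_ms[r$raster$neuron == 1]
    expect_gt(length(src_t), 0)
    t0 <- src_t[1]
    v_post <- r$v_trace[1, ] # post neuron is global id 0
    moved <- which(abs(v_post - (-65)) > 1e-12)
    expect_equal(moved[1], t0 + d)
  }
})

test_that("identical seeds give identical runs; seeds matter", {
  spec <- recurrent_spec(n = 200, duration = 100)
  r1 <- run_simulation(spec)
  r2 <- run_simulation(spec)
  expect_identical(r1$raster, r2$raster)
  expect_identical(r1$weights, r2$weights)
  spec2 <- recurrent_spec(n = 200, duration = 100, seed = 12)
  r3 <- run_simulation(spec2)
  expect_false(identical(r1$raster, r3$raster))
})

test_that("rasters and weights are invariant across partitionings", {
  spec <- recurrent_spec(n = 400, duration = 120)
  ref <- run_simulation(spec, partition_standard(spec))
  for (k in c(1, 3)) {
    r <- run_simulation(spec, partition_synapse_centric(spec, presyn_split = k))
    expect_identical(r$raster, ref$raster)
    expect_identical(r$weights$weight, ref$weights$weight)
  }
})

test_that("flush events change nothing in a static-synapse network", {
  spec <- recurrent_spec(n = 200, duration = 100)
  spec$projections$ee$plasticity <- NULL # make everything static
  spec$plasticity_configs <- list()
  spec_nf <- spec
  spec_nf$flush <- FALSE
  r1 <- run_simulation(spec)
  r2 <- run_simulation(spec_nf)
  expect_identical(r1$raster, r2$raster)
  expect_equal(r1$flush_count + r2$flush_count, 0)
})

test_that("engine plasticity matches the module-level reference and oracle", {
  p <- neuron_params(tau_m = 20, v_rest = -65, v_thresh = -50, v_reset = -65,
                     t_refrac = 5, tau_syn = c(exc = 5))
  p$i_offset <- dc_for_rate(40, p)
  cfg <- stdp_config(tau_plus = 20, tau_minus = 20, a_plus = 0.005,
                     a_minus = 0.006, w_max = 0.1)
  spec <- network_spec(
    list(population("post", 1, p),
         population("src", 1, kind = "poisson", rate = 20)),
    list(projection("in", "src", "post", p = 1, weight = 0.05, delay = 1,
                    plasticity = "r")),
    duration = 2000, max_rate = 100, seed = 21,
    plasticity_configs = list(r = cfg)
  )
  r <- run_simulation(spec)
  pre_t <- r$raster$time_ms[r$raster$neuron == 1]
  post_t <- r$raster$time_ms[r$raster$neuron == 0]
  expect_gt(length(pre_t), 10)
  expect_gt(length(post_t), 50)

  # the engine routes events with one step of latency, so events emitted at
  # the final step are never consumed: replay the same truncated trains
  ref <- deferred_stdp(pre_t[pre_t < 2000], post_t[post_t < 2000], cfg,
                       t_end = 1999, capacity = 10, flush_enabled = TRUE,
                       max_rate = 100, w0 = 0.05, terminal_flush = FALSE)
  expect_equal(r$weights$weight, ref$w, tolerance = 1e-12)
  expect_equal(r$lost_history, 0)

  t_last <- ref$row$t_last_update
  w_oracle <- oracle_stdp(pre_t[pre_t <= t_last], post_t[post_t <= t_last],
                          cfg, w0 = 0.05)
  expect_equal(r$weights$weight, w_oracle, tolerance = 1e-12)
})

test_that("realized synaptic event rates match the configured input", {
  spec <- make_poisson_benchmark(n_post = 1024, connectivity = 1,
                                 mu_input = 24000, duration = 500)
  r <- run_simulation(spec)
  syn <- r$stats[r$stats$role == "synapse", ]
  steps <- 500
  total_events <- sum(syn$mean_events) * steps
  n_src <- 2400
  p_spk <- 1 - exp(-10 * 1 / 1000)
  expected <- n_src * steps * p_spk * 1024
  sd_events <- sqrt(n_src * steps * p_spk * (1 - p_spk)) * 1024
  expect_lt(abs(total_events - expected), 3 * sd_events)
  # per-neuron input rate on the 24 kHz benchmark scale
  rate_per_neuron <- total_events / 1024 / (steps / 1000)
  expect_gt(rate_per_neuron, 22000)
  expect_lt(rate_per_neuron, 26000)
})

test_that("feasibility audit reports headroom and flags overruns", {
  # near-saturated synapse processor: ~95% of the row-aware capacity
  cap_per_neuron <- synproc_capacity(128, "static") / 128
  mu <- 0.95 * cap_per_neuron
  spec <- make_poisson_benchmark(n_post = 128, connectivity = 1,
                                 mu_input = mu, duration = 300)
  alloc <- partition_synapse_centric(spec)
  expect_equal(alloc$totals$synapse, 1)
  r <- run_simulation(spec, alloc)
  audit <- audit_allocation(alloc, r$stats)
  busy <- audit[audit$role == "synapse", ]
  util <- busy$mean_cycles / busy$budget
  expect_gt(util, 0.90)
  expect_lt(util, 1.00)
  expect_false(any(audit$overrun[audit$role == "neuron"]))

  # doubling the input rate on the same single-processor allocation
  spec2 <- make_poisson_benchmark(n_post = 128, connectivity = 1,
                                  mu_input = 2 * mu, duration = 300)
  alloc2 <- partition_synapse_centric(spec2, presyn_split = 1)
  r2 <- run_simulation(spec2, alloc2)
  audit2 <- audit_allocation(alloc2, r2$stats)
  expect_true(any(audit2$overrun[audit2$role == "synapse"]))

  # an idle network sits far under budget
  idle <- run_simulation(recurrent_spec(n = 100, duration = 50))
  a_idle <- audit_allocation(partition_synapse_centric(recurrent_spec(n = 100)),
                             idle$stats)
  expect_true(all(a_idle$headroom[a_idle$role == "neuron"] > 0.5))
})
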