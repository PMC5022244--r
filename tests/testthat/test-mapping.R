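test_that("standard-mapping cost model reproduces the published estimates", {
  # STDP model: 49 neurons/core at dt = 1 ms, 24 kHz input, h = 1
  expect_identical(estimate_standard_neurons_per_core(1, 24000, plastic = TRUE),
                   49L)
  # static model evaluates to 291 but is capped at the practical 256
  costs <- cost_constants()
  raw <- floor(costs$clock / (costs$std_per_neuron * 1000 +
                                costs$std_per_event * 24000))
  expect_equal(raw, 291)
  expect_identical(estimate_standard_neurons_per_core(1, 24000), 256L)
  expect_identical(estimate_standard_neurons_per_core(1, 0), 256L)
})

test_that("synapse-processor peak and row-aware capacities match", {
  expect_equal(synproc_capacity(kind = "static", per_row = 0), 200e6 / 15)
  expect_equal(synproc_capacity(kind = "stdp", h = 1, per_row = 0), 200e6 / 137)
  expect_equal(synproc_capacity(102.4, "static"), 200e6 / (15 + 800 / 102.4))
})

test_that("minimal synapse-processor counts reproduce the published figures", {
  # peak model (no row overhead)
  expect_identical(count_synapse_processors(1024, 24000, kind = "static",
                                            per_row = 0), 2L)
  expect_identical(count_synapse_processors(512, 24000, kind = "stdp",
                                            per_row = 0), 9L)
  # row-aware model with default overheads: 10 Hz sources
  expect_identical(count_synapse_processors(1024, 24000, rows_per_s = 240000,
                                            row_len = 102.4, kind = "static"),
                   3L)
  expect_identical(count_synapse_processors(512, 24000, rows_per_s = 120000,
                                            row_len = 102.4, kind = "stdp"),
                   10L)
  expect_error(count_synapse_processors(1024, 24000, row_len = 2048,
                                        kind = "stdp"), "infeasible")
})

test_that("count is minimal and monotone", {
  costs <- cost_constants()
  feasible <- function(k, events, rows, pe, pr) {
    (events / k) * pe + (rows / k) * pr <= costs$clock
  }
  set.seed(11)
  for (i in 1:50) {
    n_post <- sample(c(128, 256, 512, 1024), 1)
    mu <- stats::runif(1, 1e3, 5e4)
    rows <- stats::runif(1, 0, 3e5)
    kind <- sample(c("static", "stdp"), 1)
    pe <- if (kind == "static") 15 else 137
    pr <- if (kind == "static") 800 else 1500
    k <- count_synapse_processors(n_post, mu, rows, kind = kind)
    expect_true(feasible(k, n_post * mu, rows, pe, pr))
    if (k > 1) expect_false(feasible(k - 1, n_post * mu, rows, pe, pr))
  }
  # fewer processors needed as rows lengthen at fixed event rate; more as
  # event rate grows
  k_long <- count_synapse_processors(1024, 24000, rows_per_s = 24000,
                                     kind = "static")
  k_short <- count_synapse_processors(1024, 24000, rows_per_s = 240000,
                                      kind = "static")
  expect_lte(k_long, k_short)
  expect_lte(count_synapse_processors(1024, 12000, kind = "static"),
             count_synapse_processors(1024, 24000, kind = "static"))
})

test_that("synapse-centric partitioner reproduces the benchmark core counts", {
  va10 <- make_vogels_abbott(10000, 0.02)
  a10 <- partition_synapse_centric(va10)
  expect_equal(a10$totals$neuron, 10)
  expect_equal(a10$totals$synapse, 20)
  expect_equal(a10$totals$total, 30)
  expect_equal(a10$detail$exc$nsize, 1024)

  va80 <- make_vogels_abbott(80000, 0.1)
  a80 <- partition_synapse_centric(va80)
  expect_equal(a80$totals$neuron, 157)
  expect_equal(a80$totals$synapse, 314)
  expect_equal(a80$totals$total, 471)
  expect_equal(a80$detail$exc$nsize, 512) # halved: 4 synapse procs per 1024
  # every allocated core sits within its per-step cycle budget
  expect_true(all(a80$cores$cycles_per_step <= 200e6 * 1e-3))
})

test_that("tiny networks get the minimum allocation", {
  p <- neuron_params(tau_syn = c(exc = 5))
  spec <- network_spec(
    list(population("a", 50, p), population("b", 60, p)),
    list(projection("ab", "a", "b", p = 0.1, weight = 0.1)),
    duration = 10
  )
  a <- partition_synapse_centric(spec, rate_assumptions(mean_presynaptic_rate = 1))
  expect_equal(a$totals$neuron, 2) # one per population
  expect_equal(a$totals$synapse, 1)
})

test_that("standard partitioner divides neurons by the cost-model slice", {
  va10 <- make_vogels_abbott(10000, 0.02)
  s <- partition_standard(va10)
  expect_equal(s$totals$total, 40)
  expect_equal(unique(s$cores$n_items), 250)

  # plastic population at 24 kHz input: ceil(N / 49) cores
  p <- neuron_params(tau_syn = c(exc = 5))
  spec <- network_spec(
    list(population("src", 2400, p, kind = "poisson", rate = 10),
         population("post", 512, p)),
    list(projection("in", "src", "post", p = 1, weight = 0.01,
                    plasticity = "r")),
    plasticity_configs = list(r = stdp_config(w_max = 0.1)), duration = 10
  )
  s2 <- partition_standard(spec)
  expect_equal(s2$totals$neuron, ceiling(512 / 49))
  expect_equal(s2$totals$spike_source, ceiling(2400 / 1024))
})

test_that("current-input processors are allocated for background input", {
  p <- neuron_params(tau_syn = c(exc = 5))
  spec <- network_spec(
    list(population("a", 2048, p,
                    background = background_input(rate = 1000, weight = 0.01))),
    duration = 10
  )
  a <- partition_synapse_centric(spec)
  expect_equal(a$totals$neuron, 2)
  expect_equal(a$totals$current_input, 2) # one per neuron core
})

test_that("heterogeneous plasticity rules get separate synapse processors", {
  spec <- make_modular_attractor(1)
  a <- partition_synapse_centric(spec)
  syn <- a$cores[a$cores$role == "synapse" & a$cores$population == "exc", ]
  plastic_types <- unique(grep("ampa_rule|nmda_rule", syn$type, value = TRUE))
  expect_gte(length(plastic_types), 2)
})
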