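test_that("poisson benchmark source counts follow the rate arithmetic", {
  pb <- make_poisson_benchmark(n_post = 1024, connectivity = 1,
                               mu_input = 24000, source_rate = 10)
  expect_equal(pb$populations$sources$size, 2400)
  expect_equal(pb$projections$input$p, 1)

  pb10 <- make_poisson_benchmark(n_post = 1024, connectivity = 0.1,
                                 mu_input = 24000, source_rate = 10)
  expect_equal(pb10$populations$sources$size, 24000)

  # no input means no source population
  pb0 <- make_poisson_benchmark(n_post = 16, mu_input = 0)
  expect_length(pb0$populations, 1)
  expect_length(pb0$projections, 0)
})

test_that("DC calibration hits the analytic LIF rate in simulation", {
  p <- neuron_params(tau_m = 20, v_rest = -65, v_thresh = -50, v_reset = -65,
                     t_refrac = 5, tau_syn = c(exc = 5))
  expect_equal(dc_for_rate(0, p), 0)
  p$i_offset <- dc_for_rate(20, p)
  spec <- network_spec(list(population("n", 1, p)), duration = 2000)
  r <- run_simulation(spec)
  rate <- nrow(r$raster) / 2
  expect_gt(rate, 17); expect_lt(rate, 23) # grid discretization tolerance
})

test_that("Vogels-Abbott generator produces the expected structure", {
  va <- make_vogels_abbott(10000, 0.02)
  expect_equal(va$populations$exc$size, 8000)
  expect_equal(va$populations$inh$size, 2000)
  expect_length(va$projections, 4)
  expect_length(validate_network(va), 0)

  # mean in-degree: 200 at (10,000, 2%); complete graph minus self at p = 1
  m <- build_matrices(make_vogels_abbott(1000, 0.02, seed = 2))
  indeg_mu <- sum(vapply(m, function(x) sum(diff(x$pre_ptr)), numeric(1))) / 1000
  expect_lt(abs(indeg_mu - 0.02 * 999), 3 * sqrt(1000 * 0.02 * 0.98 * 2) / sqrt(1000))

  m1 <- build_matrices(make_vogels_abbott(100, 1.0))
  pairs <- sum(vapply(m1, function(x) sum(diff(x$pre_ptr)), numeric(1)))
  expect_equal(pairs, 100 * 99) # all ordered pairs, no self-connections

  # weights scale inversely with expected in-degree
  va80 <- make_vogels_abbott(80000, 0.1)
  expect_equal(va80$projections$ee$weight * 64000 * 0.1,
               va$projections$ee$weight * 8000 * 0.02)
})

test_that("the 10,000-neuron network self-sustains after stimulus removal", {
  va <- make_vogels_abbott(10000, 0.02, duration = 500, seed = 3)
  r <- run_simulation(va)
  # activity persists well past the 50 ms kick, at a plausible rate
  late <- r$raster[r$raster$time_ms > 400, ]
  expect_gt(nrow(late), 0)
  rate <- nrow(late) / 10000 / 0.1
  expect_gt(rate, 1); expect_lt(rate, 100)
})

test_that("modular attractor scales by hypercolumn and splits plastic rules", {
  a16 <- make_modular_attractor(16)
  expect_equal(a16$populations$exc$size, 16000)
  expect_equal(a16$populations$inh$size, 4000)

  a1 <- make_modular_attractor(1)
  expect_equal(a1$populations$exc$size + a1$populations$inh$size, 1250)
  expect_length(validate_network(a1), 0)

  alloc <- partition_synapse_centric(a1)
  syn_types <- unique(alloc$cores$type[alloc$cores$role == "synapse" &
                                         alloc$cores$population == "exc"])
  expect_gte(sum(grepl("_rule", syn_types)), 2)
})

test_that("sequence training strengthens forward transitions over backward", {
  spec <- make_modular_attractor(1, seed = 7)
  spec <- attractor_training_stimulus(spec, sequence = 1:6, epoch_ms = 40,
                                      n_repeats = 2)
  r <- run_simulation(spec)
  w <- r$weights[r$weights$projection == "ee_nmda", ]
  mini <- function(id) id %/% 100 + 1
  fwd <- w$weight[mini(w$post) == mini(w$pre) + 1 & mini(w$pre) <= 5]
  bwd <- w$weight[mini(w$post) == mini(w$pre) - 1 & mini(w$post) <= 5]
  expect_gt(mean(fwd), mean(bwd))
  expect_gt(mean(fwd), 0)
  # both rules trained simultaneously: the symmetric AMPA-like rule also
  # moved weights during the same run
  wa <- r$weights[r$weights$projection == "ee_ampa", ]
  expect_gt(max(wa$weight), 0)
})
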