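cfg20 <- stdp_config(tau_plus = 20, tau_minus = 20, a_plus = 0.01,
                     a_minus = 0.012, w_max = 1)

test_that("trace recurrences follow the exponential update", {
  h <- add_post_spike(post_history(), 10, cfg20)
  expect_equal(h$t, 10)
  expect_equal(h$s, 1)
  h <- add_post_spike(add_post_spike(post_history(), 0, cfg20), 20, cfg20)
  expect_equal(h$s[2], exp(-1) + 1)

  expect_equal(add_pre_spike(0, 5, NA, cfg20), 1)
  expect_equal(add_pre_spike(1, 20, 0, cfg20), exp(-1) + 1)
  expect_equal(add_pre_spike(1, 1e6, 0, cfg20), 1) # full decay limit
})

test_that("history queue drops oldest entries on overflow and counts them", {
  h <- post_history(capacity = 10)
  for (t in 1:11) h <- add_post_spike(h, t, cfg20)
  expect_length(h$t, 10)
  expect_equal(h$t[1], 2) # oldest dropped
  expect_equal(h$lost, 1L)
  expect_error(add_post_spike(h, 5, cfg20), "time order")
})

test_that("pair updates evaluate the STDP kernel with clipping", {
  # potentiation: w=0, s_i=1, dt=10, tau+=20, a+=0.01
  expect_equal(apply_post_spike(0, 10, 0, 1, cfg20), 0.01 * exp(-0.5))
  expect_equal(apply_post_spike(0.3, 10, NA, 1, cfg20), 0.3) # no pre yet
  expect_equal(apply_post_spike(0.9999999, 0, 0, 50, cfg20), 1) # clip at w_max

  # depression: w=0.01, s_j=1, dt=20, tau-=20, a-=0.012
  expect_equal(apply_pre_spike(0.01, 20, 0, 1, cfg20), 0.01 - 0.012 * exp(-1))
  expect_equal(apply_pre_spike(0.01, 20, NA, NA, cfg20), 0.01) # empty history
  expect_equal(apply_pre_spike(0.001, 0, 0, 5, cfg20), 0) # clip at zero
})

test_that("process_row implements the deferred algorithm", {
  # flush: history replayed, no insertion, t_last_spike untouched
  row <- synaptic_row(post = 1:2, delay = 1, weight = 0.5)
  hist <- list(post_history(), post_history())
  ring <- ring_buffer(2)
  res <- process_row(5, TRUE, row, hist, ring, cfg20)
  expect_identical(res$ring$slots, ring$slots)
  expect_true(is.na(res$row$t_last_spike))
  expect_equal(res$row$t_last_update, 5)

  # empty histories, real spike: weights inserted unchanged, s_i updated
  res <- process_row(5, FALSE, row, hist, ring, cfg20)
  expect_equal(res$row$s_i, 1)
  expect_equal(res$row$t_last_spike, 5)
  expect_equal(ring_drain(res$ring)$input, c(0.5, 0.5))

  # events must arrive in time order
  expect_error(process_row(1, FALSE, res$row, hist, NULL, cfg20),
               "time order")
})

test_that("a deferred pre/post/pre triplet matches the online oracle exactly", {
  # pre at 0, post at 10, pre at 30 (tau = 20 ms, a+ = a- = 0.01)
  cfg <- stdp_config(tau_plus = 20, tau_minus = 20, a_plus = 0.01,
                     a_minus = 0.01, w_max = 1)
  w_oracle <- oracle_stdp(c(0, 30), 10, cfg, w0 = 0.5)
  # hand-derived: potentiation 0.01*exp(-10/20), then depression
  # 0.01*exp(-20/20) against the post trace of 1
  expect_equal(w_oracle, 0.5 + 0.01 * exp(-0.5) - 0.01 * exp(-1))

  row <- synaptic_row(post = 1, delay = 1, weight = 0.5)
  hist <- list(post_history())
  row <- process_row(0, FALSE, row, hist, NULL, cfg)$row
  hist[[1]] <- add_post_spike(hist[[1]], 10, cfg)
  row <- process_row(30, FALSE, row, hist, NULL, cfg)$row
  expect_equal(row$weight, w_oracle)
})

test_that("deferred updates with unbounded history equal the online oracle", {
  cfg <- stdp_config(tau_plus = 18, tau_minus = 23, a_plus = 0.008,
                     a_minus = 0.01, w_max = 0.5)
  for (i in 1:40) {
    pre <- poisson_train(stats::runif(1, 5, 50), 3000, 300 + i)
    post <- poisson_train(stats::runif(1, 5, 50), 3000, 900 + i)
    wd <- deferred_stdp(pre, post, cfg, 3000, w0 = 0.25)
    expect_identical(wd$w, oracle_stdp(pre, post, cfg, w0 = 0.25))
    expect_true(wd$w >= 0 && wd$w <= cfg$w_max)
  }
})

test_that("a lone presynaptic spike never changes the weight", {
  row <- synaptic_row(post = 1, delay = 1, weight = 0.3)
  res <- process_row(100, FALSE, row, list(post_history()), NULL, cfg20)
  expect_equal(res$row$weight, 0.3)
})

test_that("flush timing follows the silence threshold and re-arms", {
  pol <- flush_policy(max_rate = 100, buffer_size = 10)
  expect_equal(pol$threshold_ms, 100)
  expect_false(flush_check(99, 0, pol))
  expect_true(flush_check(100, 0, pol))

  # a neuron firing at max_rate never flushes
  t_last <- 0
  flushes <- 0
  for (tm in 1:2000) {
    if (tm %% 10 == 0) t_last <- tm # spike every 10 ms = 100 Hz
    else if (flush_check(tm, t_last, pol)) { flushes <- flushes + 1; t_last <- tm }
  }
  expect_equal(flushes, 0)

  # a silent neuron flushes every threshold: 10 times in a second
  t_last <- 0; flushes <- 0
  for (tm in 1:1000) {
    if (flush_check(tm, t_last, pol)) { flushes <- flushes + 1; t_last <- tm }
  }
  expect_equal(flushes, 10)
})
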