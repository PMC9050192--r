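test_that("the STDP window has the standard amplitudes and exponential
           shape", {
  p <- stdp_params()
  expect_equal(stdp_window(-1e-9, p), 0.925, tolerance = 1e-6)
  expect_equal(stdp_window(1e-9, p), -0.1, tolerance = 1e-6)
  expect_equal(stdp_window(0, p), 0)
  expect_equal(stdp_window(-20, p), 0.925 * exp(-1), tolerance = 1e-12)
  # exact exponential decay on both branches
  dts <- seq(1, 80, by = 0.5)
  expect_equal(stdp_window(-dts, p), 0.925 * exp(-dts / 20),
               tolerance = 1e-12)
  expect_equal(stdp_window(dts, p), -0.1 * exp(-dts / 20),
               tolerance = 1e-12)
  # sign and monotone-magnitude structure
  expect_true(all(stdp_window(-dts, p) > 0))
  expect_true(all(stdp_window(dts, p) < 0))
  expect_true(all(diff(abs(stdp_window(-dts, p))) < 0))
  expect_true(all(diff(abs(stdp_window(dts, p))) < 0))
})

test_that("eligibility traces decay exponentially and stay zero without
           spikes", {
  syn <- synapse_matrix(1, 1, weights = matrix(0, 1, 1), tau_e = 5)
  syn$traces[1, 1] <- 2
  hist <- spike_history(1, 1)
  for (t in 1:10) {
    res <- accumulate_trace(syn, 0L, 0L, hist)
    syn <- res$syn
    hist <- res$history
  }
  expect_equal(syn$traces[1, 1], 2 * exp(-10 / 5), tolerance = 1e-12)

  syn0 <- synapse_matrix(2, 2, weights = matrix(0, 2, 2))
  res <- accumulate_trace(syn0, c(0L, 0L), c(0L, 0L), spike_history(2, 2))
  expect_equal(res$syn$traces, matrix(0, 2, 2))
  expect_error(accumulate_trace(syn0, c(0L, 0L), c(0L, 0L),
                                spike_history(2, 2), dt = -1), "positive")
})

test_that("a pre spike 5 ms before a post spike leaves the hand-integrated
           trace", {
  syn <- synapse_matrix(1, 1, weights = matrix(0, 1, 1), tau_e = 5)
  hist <- spike_history(1, 1)
  T_len <- 12
  for (t in 1:T_len) {
    pre <- as.integer(t == 3)
    post <- as.integer(t == 8)
    res <- accumulate_trace(syn, pre, post, hist)
    syn <- res$syn
    hist <- res$history
  }
  # jump of STDP(-5) at t = 8, pure decay afterwards
  expected <- 0.925 * exp(-5 / 20) * exp(-(T_len - 8) / 5)
  expect_equal(syn$traces[1, 1], expected, tolerance = 1e-12)
})

test_that("window traces match the independent event-pairing oracle on
           random rasters", {
  set.seed(4)
  for (i in 1:8) {
    T_len <- 25
    pre <- rbinom(T_len, 1, 0.3)
    post <- rbinom(T_len, 1, 0.3)
    got <- window_trace(matrix(pre, 1), matrix(post, 1))[1, 1]
    want <- oracle_window_trace(which(pre == 1), which(post == 1), T_len)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("apply_reward is the clipped discrete rule and is antisymmetric
           in the reward", {
  syn <- synapse_matrix(2, 2, weights = matrix(0.2, 2, 2),
                        learning_rate = 0.1)
  syn$traces[] <- 0.5
  up <- apply_reward(syn, 1)
  expect_equal(up$weights, matrix(0.25, 2, 2))
  expect_equal(apply_reward(syn, 0)$weights, syn$weights)
  down <- apply_reward(syn, -1)
  expect_equal(up$weights - syn$weights, -(down$weights - syn$weights))

  # clipping keeps weights in [-1, 1] under any update sequence
  syn$traces[] <- 50
  expect_true(all(abs(apply_reward(syn, 1)$weights) <= 1))
  expect_true(all(abs(apply_reward(syn, -1)$weights) <= 1))
  set.seed(5)
  s2 <- synapse_matrix(3, 3)
  for (i in 1:50) {
    s2$traces <- matrix(rnorm(9, sd = 3), 3, 3)
    s2 <- apply_reward(s2, rnorm(1, sd = 2))
    expect_true(all(s2$weights >= -1 & s2$weights <= 1))
  }
})

test_that("unsupervised STDP potentiates pre-before-post, depresses the
           reverse, and matches the pairing oracle", {
  T_len <- 20
  spike_at <- function(t) {
    m <- matrix(0L, 1, T_len)
    m[1, t] <- 1L
    m
  }
  syn <- synapse_matrix(1, 1, weights = matrix(0, 1, 1))
  expect_gt(unsupervised_stdp_update(syn, spike_at(10),
                                     spike_at(11))$weights[1, 1], 0)
  expect_lt(unsupervised_stdp_update(syn, spike_at(11),
                                     spike_at(10))$weights[1, 1], 0)

  set.seed(6)
  for (i in 1:6) {
    pre <- rbinom(T_len, 1, 0.35)
    post <- rbinom(T_len, 1, 0.35)
    syn <- synapse_matrix(1, 1, weights = matrix(0, 1, 1),
                          learning_rate = 0.05)
    got <- unsupervised_stdp_update(syn, matrix(pre, 1),
                                    matrix(post, 1))$weights[1, 1]
    want <- max(min(0.05 * oracle_pair_sum(which(pre == 1), which(post == 1)),
                    1), -1)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(unsupervised_stdp_update(syn, matrix(0L, 1, 5),
                                        matrix(0L, 1, 6)), "same steps")
})

test_that("the tonic-input fast paths agree with the general forward and
           trace implementations", {
  set.seed(7)
  n_in <- 30; n_out <- 12; T_len <- 24
  w <- matrix(runif(n_out * n_in, -0.5, 1), n_out, n_in)
  active <- sort(sample(n_in, 12))
  raster <- matrix(0L, n_in, T_len)
  raster[active, ] <- 1L
  p <- neuron_params()
  fast <- tomsnn:::.tonic_forward(w, active, T_len, p, gain = 25)
  slow <- forward_window(w, raster, window_config(T_len), params = p,
                         gain = 25)
  expect_equal(fast, unclass(slow)[, ], ignore_attr = TRUE)

  tv <- tomsnn:::.tonic_trace_vec(fast, 5, 1, stdp_params())
  full <- window_trace(raster, fast)
  expect_equal(full[, active], matrix(tv, n_out, length(active)),
               tolerance = 1e-12)
  expect_true(all(full[, -active] == 0))
})
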