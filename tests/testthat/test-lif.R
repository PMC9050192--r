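test_that("membrane at rest with no input is a fixed point, and threshold
           crossing fires and resets", {
  p <- neuron_params()
  st <- lif_layer_state(3, p)
  res <- lif_step(st, c(0, 0, 0))
  expect_equal(res$state$potentials, rep(p$v_rest, 3))
  expect_equal(res$spikes, c(0L, 0L, 0L))

  # a current strong enough to cross -55 mV in one step fires and resets
  strong <- (p$v_threshold - p$v_rest) / (1 - exp(-p$dt / p$tau_m)) + 1
  res <- lif_step(lif_layer_state(1, p), strong)
  expect_equal(res$spikes, 1L)
  expect_equal(res$state$potentials, p$v_rest)

  expect_error(lif_step(lif_layer_state(2, p), 1), "length")
})

test_that("with zero input the potential decays exponentially toward rest", {
  p <- neuron_params()
  st <- lif_layer_state(1, p)
  st$potentials <- -60
  v <- numeric(10)
  for (t in 1:10) {
    res <- lif_step(st, 0)
    st <- res$state
    v[t] <- st$potentials
  }
  expect_equal(v, p$v_rest + (-60 - p$v_rest) * exp(-(1:10) / p$tau_m),
               tolerance = 1e-12)
  expect_true(all(diff(v) < 0)) # monotone decay toward rest
})

test_that("inter-spike intervals under constant current match the analytic
           first-passage time within one step", {
  p <- neuron_params()
  dv <- p$v_threshold - p$v_rest
  for (ri in c(21, 22, 25, 30, 40, 60, 100, 200, 400)) {
    st <- lif_layer_state(1, p)
    times <- integer(0)
    for (t in 1:400) {
      res <- lif_step(st, ri)
      st <- res$state
      if (res$spikes == 1L) times <- c(times, t)
    }
    analytic <- p$tau_m * log(ri / (ri - dv))
    expect_true(length(times) >= 2)
    expect_true(all(abs(diff(times) - analytic) <= p$dt),
                label = sprintf("RI = %g", ri))
  }
})

test_that("potentials never exceed threshold after a completed step", {
  p <- neuron_params()
  st <- lif_layer_state(20, p)
  set.seed(1)
  for (t in 1:80) {
    res <- lif_step(st, runif(20, -50, 450))
    st <- res$state
    expect_true(all(st$potentials < p$v_threshold))
  }
})

test_that("integrate_input equals the brute-force weighted double loop", {
  set.seed(2)
  w <- matrix(runif(6 * 10, -1, 1), 6, 10)
  s <- rbinom(10, 1, 0.4)
  manual <- vapply(1:6, function(j) sum(w[j, ] * s), numeric(1))
  expect_equal(integrate_input(w, s), manual)
  expect_equal(integrate_input(w, rep(0L, 10)), rep(0, 6))
  expect_equal(integrate_input(matrix(1, 4, 5), c(1, 1, 1, 0, 0), gain = 2),
               rep(6, 4)) # three spikes through unit weights, gain 2
  expect_error(integrate_input(w, c(1, 0)), "inputs")
})

test_that("forward_window reproduces the scalar LIF simulation and is
           deterministic", {
  p <- neuron_params()
  w <- matrix(3, 1, 1) # one strong synapse
  raster <- matrix(1L, 1, 40)
  out <- forward_window(w, raster, window_config(40), params = p, gain = 20)
  # scalar oracle: same constant current through lif_step
  st <- lif_layer_state(1, p)
  oracle <- integer(40)
  for (t in 1:40) {
    res <- lif_step(st, 60)
    st <- res$state
    oracle[t] <- res$spikes
  }
  expect_equal(as.integer(out), oracle)
  expect_identical(out, forward_window(w, raster, window_config(40),
                                       params = p, gain = 20))

  # zero weights produce an empty raster
  expect_equal(sum(forward_window(matrix(0, 2, 3), matrix(1L, 3, 10),
                                  window_config(10))), 0)
  expect_error(forward_window(w, raster, window_config(50)), "steps")
})

test_that("spike counts are non-decreasing in the window length for
           periodic input", {
  w <- matrix(0.5, 2, 4)
  raster <- matrix(rep(c(1L, 0L), 30), 4, 30, byrow = TRUE)
  counts <- vapply(c(5, 10, 20, 30), function(T_len) {
    sum(forward_window(w, raster, window_config(T_len), gain = 60))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("population_counts matches the nested-sum oracle and conserves
           total spikes", {
  part <- population_partition(c("a", "b"), 2L)
  r <- matrix(0L, 4, 5)
  r[1, 1:3] <- 1L # neuron 1: 3 spikes
  r[2, 5] <- 1L   # neuron 2: 1 spike
  r[4, 2:3] <- 1L # neuron 4: 2 spikes
  expect_equal(population_counts(r, part), c(a = 4, b = 2))
  expect_equal(population_counts(matrix(0L, 4, 5), part), c(a = 0, b = 0))

  set.seed(3)
  for (i in 1:10) {
    P <- sample(2:4, 1)
    J <- sample(2:5, 1)
    T_len <- sample(5:20, 1)
    raster <- matrix(rbinom(P * J * T_len, 1, 0.3), P * J, T_len)
    part <- population_partition(letters[1:P], J)
    counts <- population_counts(raster, part)
    oracle <- numeric(P)
    for (pp in 1:P) {
      for (j in 1:J) {
        for (t in 1:T_len) oracle[pp] <- oracle[pp] + raster[(pp - 1) * J + j, t]
      }
    }
    expect_equal(unname(counts), oracle)
    expect_equal(sum(counts), sum(raster))
  }
})

test_that("winner_population takes the argmax with lowest-index ties", {
  part <- population_partition(c("x", "y", "z"), 2L)
  expect_equal(winner_population(c(3, 7, 2), part), "y")
  expect_equal(winner_population(c(5, 5, 1), part), "x")
  expect_equal(winner_population(4, population_partition("only", 1L)), "only")
  expect_error(winner_population(numeric(0), part), "empty")
})
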