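#' LIF neuron parameters
#'
#' Parameters of the leaky integrate-and-fire membrane equation
#' \deqn{\tau_m \, dV/dt = -(V - V_{rest}) + R I(t)}
#' integrated with step `dt`. Defaults are the model's standard values:
#' threshold -55 mV, rest -75 mV, membrane time constant 20 ms, dimensionless
#' membrane resistance R = 1.
#'
#' @param v_threshold spike threshold (mV).
#' @param v_rest resting/reset potential (mV); must be below `v_threshold`.
#' @param tau_m membrane time constant (ms), > 0.
#' @param membrane_resistance dimensionless current-to-potential scale.
#' @param dt integration step (ms), > 0.
#' @return an object of class `neuron_params`.
#' @export
neuron_params <- function(v_threshold = -55, v_rest = -75, tau_m = 20,
                          membrane_resistance = 1, dt = 1) {
  if (!(v_threshold > v_rest)) .stopf("v_threshold must exceed v_rest")
  if (!(tau_m > 0)) .stopf("tau_m must be positive")
  if (!(dt > 0)) .stopf("dt must be positive")
  structure(
    list(v_threshold = v_threshold, v_rest = v_rest, tau_m = tau_m,
         membrane_resistance = membrane_resistance, dt = dt),
    class = "neuron_params"
  )
}

#' LIF layer state
#'
#' Membrane potentials of one layer of LIF neurons, all initialised at rest.
#'
#' @param n number of neurons.
#' @param params a [neuron_params()] object.
#' @return an object of class `lif_layer_state` with fields `potentials` and
#'   `params`.
#' @export
lif_layer_state <- function(n, params = neuron_params()) {
  structure(
    list(potentials = rep(params$v_rest, n), params = params),
    class = "lif_layer_state"
  )
}

#' @export
print.lif_layer_state <- function(x, ...) {
  cat(sprintf("<lif_layer_state> %d neurons, V in [%.2f, %.2f] mV\n",
              length(x$potentials), min(x$potentials), max(x$potentials)))
  invisible(x)
}

#' Advance a LIF layer by one time step
#'
#' Integrates the membrane equation over one step `dt` holding the input
#' current constant, using the exact exponential solution of the linear ODE:
#' \deqn{V \leftarrow V_{rest} + RI + (V - V_{rest} - RI)\,e^{-dt/\tau_m}.}
#' Neurons whose updated potential reaches `v_threshold` emit a spike and are
#' hard-reset to `v_rest` (no refractory period).
#'
#' @param state a [lif_layer_state()].
#' @param input_current numeric vector of input currents, one per neuron.
#' @return a list with elements `state` (updated layer) and `spikes`
#'   (integer 0/1 vector).
#' @export
lif_step <- function(state, input_current) {
  n <- length(state$potentials)
  if (length(input_current) != n) {
    .stopf("input_current has length %d but layer has %d neurons",
           length(input_current), n)
  }
  p <- state$params
  v_inf <- p$v_rest + p$membrane_resistance * input_current
  decay <- exp(-p$dt / p$tau_m)
  v <- v_inf + (state$potentials - v_inf) * decay
  fired <- v >= p$v_threshold
  v[fired] <- p$v_rest
  state$potentials <- v
  list(state = state, spikes = as.integer(fired))
}

#' Spike raster constructor
#'
#' A binary record of spikes, neurons x time steps.
#'
#' @param spikes binary matrix (neurons x steps).
#' @param dt time step (ms).
#' @return an object of class `spike_raster` (a matrix with a `dt` attribute).
#' @export
spike_raster <- function(spikes, dt = 1) {
  spikes <- as.matrix(spikes)
  if (length(spikes) && !all(spikes %in% c(0L, 1L))) {
    .stopf("spike raster entries must be 0 or 1")
  }
  structure(spikes, dt = dt, class = c("spike_raster", "matrix", "array"))
}

#' Window configuration
#'
#' Length of the simulation window over which one decision is made. The
#' network is freshly initialised at rest at the start of every window and
#' the population spike counts are accumulated over the `T` steps.
#'
#' @param window_length number of steps `T` (>= 1).
#' @return an object of class `window_config`.
#' @export
window_config <- function(window_length = 50L) {
  window_length <- as.integer(window_length)
  if (window_length < 1L) .stopf("window_length must be >= 1")
  structure(list(window_length = window_length), class = "window_config")
}

#' Population partition of an output layer
#'
#' Divides `P * J` output neurons into `P` consecutive populations of `J`
#' neurons each, one semantic label per population.
#'
#' @param labels character vector of distinct population labels.
#' @param neurons_per_population neurons per population `J`.
#' @return an object of class `population_partition`.
#' @export
population_partition <- function(labels, neurons_per_population = 6L) {
  if (anyDuplicated(labels)) .stopf("population labels must be distinct")
  structure(
    list(labels = as.character(labels),
         population_count = length(labels),
         neurons_per_population = as.integer(neurons_per_population)),
    class = "population_partition"
  )
}

#' Weighted input current to the output layer
#'
#' The current into output neuron j is the weighted sum of presynaptic
#' spikes, \eqn{I_j = g \sum_i w_{ji} S_i}, with a configurable input gain g.
#'
#' @param weights a [synapse_matrix()] or a plain weight matrix
#'   (outputs x inputs).
#' @param presyn_spikes binary spike vector of the input layer.
#' @param gain input gain (dimensionless), default 1.
#' @return numeric current vector, one per output neuron.
#' @export
integrate_input <- function(weights, presyn_spikes, gain = 1) {
  w <- if (inherits(weights, "synapse_matrix")) weights$weights else weights
  if (ncol(w) != length(presyn_spikes)) {
    .stopf("weight matrix has %d inputs but spike vector has length %d",
           ncol(w), length(presyn_spikes))
  }
  gain * as.vector(w %*% presyn_spikes)
}

#' Run a two-layer feed-forward window
#'
#' Feeds an input spike raster through the synaptic weights into a layer of
#' LIF neurons for `T` steps and records the output raster. The output layer
#' starts at rest at every window; input-layer neurons are treated as forced
#' spike sources (their raster is given, not simulated).
#'
#' @param weights a [synapse_matrix()] or plain weight matrix
#'   (outputs x inputs).
#' @param input_raster binary input raster (inputs x steps), at least `T`
#'   steps long.
#' @param cfg a [window_config()].
#' @param params a [neuron_params()] for the output layer.
#' @param gain input gain applied to the integrated current.
#' @return the output [spike_raster()] (outputs x T).
#' @export
forward_window <- function(weights, input_raster, cfg = window_config(),
                           params = neuron_params(), gain = 1) {
  w <- if (inherits(weights, "synapse_matrix")) weights$weights else weights
  T_len <- cfg$window_length
  if (ncol(input_raster) < T_len) {
    .stopf("input raster has %d steps, window needs %d",
           ncol(input_raster), T_len)
  }
  if (nrow(input_raster) != ncol(w)) {
    .stopf("input raster has %d neurons but weights expect %d",
           nrow(input_raster), ncol(w))
  }
  n_out <- nrow(w)
  out <- matrix(0L, n_out, T_len)
  state <- lif_layer_state(n_out, params)
  for (t in seq_len(T_len)) {
    res <- lif_step(state, gain * as.vector(w %*% input_raster[, t]))
    state <- res$state
    out[, t] <- res$spikes
  }
  spike_raster(out, dt = params$dt)
}

# Fast path for the common case of a tonic (constant) input pattern: active
# channels fire every step, so the input current is constant over the window
# and only the output-layer recurrence needs stepping.
.lif_tonic_raster <- function(current, T_len, params) {
  n <- length(current)
  v_inf <- params$v_rest + params$membrane_resistance * current
  decay <- exp(-params$dt / params$tau_m)
  v <- rep(params$v_rest, n)
  out <- matrix(0L, n, T_len)
  for (t in seq_len(T_len)) {
    v <- v_inf + (v - v_inf) * decay
    fired <- v >= params$v_threshold
    if (any(fired)) {
      v[fired] <- params$v_rest
      out[fired, t] <- 1L
    }
  }
  out
}

.tonic_forward <- function(w, active_idx, T_len, params, gain, bias = 0) {
  current <- if (length(active_idx)) {
    gain * rowSums(w[, active_idx, drop = FALSE])
  } else {
    numeric(nrow(w))
  }
  .lif_tonic_raster(current + bias, T_len, params)
}

# Background bias currents for one output layer: J evenly spaced levels
# repeated across populations. The spread dithers the spike-count
# quantisation so that population counts read out the underlying synaptic
# drive faithfully; the offset keeps every population in the responsive
# range (negative net drives would otherwise all read as zero).
.bias_levels <- function(P, J, range = c(25, 65)) {
  rep(seq(range[1], range[2], length.out = J), P)
}

#' Total spikes per output population
#'
#' Sums all spikes of all neurons within each population over the window,
#' \eqn{c_p = \sum_j \sum_t S^{out}_j(t)}.
#'
#' @param raster output spike raster (neurons x steps).
#' @param partition a [population_partition()] covering all raster rows.
#' @return named integer vector of per-population spike counts.
#' @export
population_counts <- function(raster, partition) {
  P <- partition$population_count
  J <- partition$neurons_per_population
  if (nrow(raster) != P * J) {
    .stopf("raster has %d neurons but partition covers %d",
           nrow(raster), P * J)
  }
  totals <- rowSums(raster)
  counts <- as.vector(rowsum(totals, rep(seq_len(P), each = J)))
  names(counts) <- partition$labels
  counts
}

#' Winner-take-all population readout
#'
#' Returns the label of the population with the most spikes; ties are broken
#' deterministically in favour of the lowest population index.
#'
#' @param counts per-population spike counts (length `P`).
#' @param partition a [population_partition()].
#' @return the winning population's label.
#' @export
winner_population <- function(counts, partition) {
  if (length(counts) == 0L) .stopf("empty count vector")
  if (length(counts) != partition$population_count) {
    .stopf("counts length %d does not match %d populations",
           length(counts), partition$population_count)
  }
  partition$labels[which.max(counts)]
}
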