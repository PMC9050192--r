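#' STDP parameters
#'
#' Amplitudes and time constants of the asymmetric STDP window. Defaults are
#' the model's standard values: A+ = 0.925, A- = 0.1,
#' tau+ = tau- = 20 ms.
#'
#' @param a_plus LTP amplitude (>= 0).
#' @param a_minus LTD amplitude (>= 0).
#' @param tau_plus LTP time constant (ms, > 0).
#' @param tau_minus LTD time constant (ms, > 0).
#' @return an object of class `stdp_params`.
#' @export
stdp_params <- function(a_plus = 0.925, a_minus = 0.1,
                        tau_plus = 20, tau_minus = 20) {
  if (a_plus < 0 || a_minus < 0) .stopf("STDP amplitudes must be >= 0")
  if (tau_plus <= 0 || tau_minus <= 0) .stopf("STDP time constants must be > 0")
  structure(list(a_plus = a_plus, a_minus = a_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus),
            class = "stdp_params")
}

#' The STDP window function
#'
#' Synaptic modification as a function of the pre-minus-post spike time
#' difference \eqn{\Delta t = t_{pre} - t_{post}}:
#' \deqn{STDP(\Delta t) = A_+ e^{\Delta t/\tau_+}\ (\Delta t < 0),\quad
#'       -A_- e^{-\Delta t/\tau_-}\ (\Delta t > 0),}
#' i.e. pre-before-post potentiates (LTP) and post-before-pre depresses
#' (LTD). Exactly coincident spikes (\eqn{\Delta t = 0}) contribute zero by
#' convention, making the function total.
#'
#' @param delta_t time difference(s) in ms; vectorised.
#' @param params an [stdp_params()] object.
#' @return numeric vector of window values.
#' @export
stdp_window <- function(delta_t, params = stdp_params()) {
  out <- numeric(length(delta_t))
  neg <- delta_t < 0
  pos <- delta_t > 0
  out[neg] <- params$a_plus * exp(delta_t[neg] / params$tau_plus)
  out[pos] <- -params$a_minus * exp(-delta_t[pos] / params$tau_minus)
  out
}

#' Synapse matrix with eligibility traces
#'
#' Weights of a fully connected input-to-output projection together with a
#' matching matrix of eligibility traces. Weights live in the closed
#' interval [-1, 1] (enforced by every update); traces decay with time
#' constant `tau_e` and collect STDP impulses at spike-pairing events.
#'
#' @param n_out number of output neurons.
#' @param n_in number of input neurons.
#' @param weights optional initial weight matrix (outputs x inputs); if
#'   `NULL`, weights are drawn uniformly from `init_range` using the current
#'   RNG state.
#' @param init_range range for uniform weight initialisation.
#' @param tau_e eligibility trace time constant (ms), default 5.
#' @param learning_rate scale of the discrete weight update, default 0.1.
#' @return an object of class `synapse_matrix`.
#' @export
synapse_matrix <- function(n_out, n_in, weights = NULL,
                           init_range = c(0, 0.3),
                           tau_e = 5, learning_rate = 0.1) {
  if (is.null(weights)) {
    weights <- matrix(runif(n_out * n_in, init_range[1], init_range[2]),
                      n_out, n_in)
  } else {
    weights <- as.matrix(weights)
    if (nrow(weights) != n_out || ncol(weights) != n_in) {
      .stopf("weights must be %d x %d", n_out, n_in)
    }
  }
  if (any(weights < -1 | weights > 1)) .stopf("weights must lie in [-1, 1]")
  if (tau_e <= 0) .stopf("tau_e must be positive")
  structure(
    list(weights = weights, traces = matrix(0, n_out, n_in),
         tau_e = tau_e, learning_rate = learning_rate),
    class = "synapse_matrix"
  )
}

#' @export
print.synapse_matrix <- function(x, ...) {
  cat(sprintf("<synapse_matrix> %d x %d, weights in [%.3f, %.3f], tau_e=%g ms\n",
              nrow(x$weights), ncol(x$weights),
              min(x$weights), max(x$weights), x$tau_e))
  invisible(x)
}

#' Create an empty spike history for incremental trace accumulation
#'
#' @param n_in,n_out input and output layer sizes.
#' @return a `spike_history` list tracking the most recent pre- and
#'   postsynaptic spike time per neuron (`NA` before the first spike) and the
#'   current time.
#' @export
spike_history <- function(n_in, n_out) {
  structure(list(last_pre = rep(NA_real_, n_in),
                 last_post = rep(NA_real_, n_out),
                 time = 0),
            class = "spike_history")
}

#' Advance eligibility traces by one time step
#'
#' Implements the trace dynamics
#' \deqn{\dot e = -e/\tau_e + STDP(\Delta t)\,\delta(t - t_{pre/post}):}
#' traces first decay by `exp(-dt/tau_e)`, then every spike occurring in this
#' step adds the STDP window value of its nearest-neighbour pairing. Pairing
#' is nearest-neighbour with the most recent strictly earlier opposite-side
#' spike; coincident (same-step) pairs contribute zero.
#'
#' @param syn a [synapse_matrix()].
#' @param pre_spikes binary spike vector of the input layer at this step.
#' @param post_spikes binary spike vector of the output layer at this step.
#' @param history a [spike_history()] covering all earlier steps.
#' @param dt step length (ms), > 0.
#' @param params an [stdp_params()].
#' @return list with updated `syn` and `history`.
#' @export
accumulate_trace <- function(syn, pre_spikes, post_spikes, history,
                             dt = 1, params = stdp_params()) {
  if (dt <= 0) .stopf("dt must be positive")
  if (length(pre_spikes) != ncol(syn$weights) ||
      length(post_spikes) != nrow(syn$weights)) {
    .stopf("spike vectors do not match synapse dimensions")
  }
  t_now <- history$time + dt
  e <- syn$traces * exp(-dt / syn$tau_e)

  post_idx <- which(post_spikes > 0)
  if (length(post_idx)) {
    # LTP: each post spike pairs with the most recent earlier pre spike.
    dtp <- history$last_pre - t_now # < 0 where a pre spike exists
    has_pre <- !is.na(dtp)
    if (any(has_pre)) {
      ltp <- numeric(length(dtp))
      ltp[has_pre] <- stdp_window(dtp[has_pre], params)
      e[post_idx, ] <- e[post_idx, , drop = FALSE] +
        matrix(ltp, length(post_idx), length(ltp), byrow = TRUE)
    }
  }
  pre_idx <- which(pre_spikes > 0)
  if (length(pre_idx)) {
    # LTD: each pre spike pairs with the most recent earlier post spike.
    dtm <- t_now - history$last_post # > 0 where a post spike exists
    has_post <- !is.na(dtm)
    if (any(has_post)) {
      ltd <- numeric(length(dtm))
      ltd[has_post] <- stdp_window(dtm[has_post], params)
      e[, pre_idx] <- e[, pre_idx, drop = FALSE] +
        matrix(ltd, length(ltd), length(pre_idx))
    }
  }
  history$last_pre[pre_idx] <- t_now
  history$last_post[post_idx] <- t_now
  history$time <- t_now
  syn$traces <- e
  list(syn = syn, history = history)
}

#' Eligibility trace accumulated over a whole window
#'
#' Convenience form of [accumulate_trace()]: starts from zero traces at the
#' beginning of the window and returns the trace matrix at the end of it,
#' given complete pre and post spike rasters.
#'
#' @param pre_raster binary raster (inputs x T).
#' @param post_raster binary raster (outputs x T).
#' @param tau_e trace time constant (ms).
#' @param dt step length (ms).
#' @param params an [stdp_params()].
#' @return trace matrix (outputs x inputs) at the end of the window.
#' @export
window_trace <- function(pre_raster, post_raster, tau_e = 5, dt = 1,
                         params = stdp_params()) {
  syn <- synapse_matrix(nrow(post_raster), nrow(pre_raster),
                        weights = matrix(0, nrow(post_raster), nrow(pre_raster)),
                        tau_e = tau_e)
  hist <- spike_history(nrow(pre_raster), nrow(post_raster))
  for (t in seq_len(ncol(pre_raster))) {
    res <- accumulate_trace(syn, pre_raster[, t], post_raster[, t], hist,
                            dt = dt, params = params)
    syn <- res$syn
    hist <- res$history
  }
  syn$traces
}

# Window trace for a tonic input pattern (active channels fire every step):
# all active input columns share one per-output-neuron trace value, computed
# in closed form from the post spike times. Equals window_trace() on the
# corresponding rasters (tested), at a fraction of the cost.
.tonic_trace_vec <- function(post_raster, tau_e, dt, params) {
  T_len <- ncol(post_raster)
  tt <- seq_len(T_len)
  decay_to_end <- exp(-(T_len - tt) * dt / tau_e)
  # LTP: post spike at t pairs with the tonic pre spike at t - 1 (t >= 2).
  ltp_gain <- params$a_plus * exp(-dt / params$tau_plus)
  ltp <- if (T_len >= 2) {
    as.vector(post_raster[, -1, drop = FALSE] %*% decay_to_end[-1]) * ltp_gain
  } else {
    numeric(nrow(post_raster))
  }
  # LTD: the tonic pre spike at u pairs with the most recent post at t < u.
  ltd <- numeric(nrow(post_raster))
  for (j in seq_len(nrow(post_raster))) {
    spk <- post_raster[j, ] > 0
    if (!any(spk)) next
    lp <- cummax(ifelse(spk, tt, 0L))
    lp_prev <- c(0L, lp[-T_len])
    valid <- lp_prev > 0L
    if (any(valid)) {
      ltd[j] <- -params$a_minus *
        sum(exp(-(tt[valid] - lp_prev[valid]) * dt / params$tau_minus) *
              decay_to_end[valid])
    }
  }
  ltp + ltd
}

#' Reward signal
#'
#' @param value finite scalar reward (dopamine analogue).
#' @return an object of class `reward_signal`.
#' @export
reward_signal <- function(value) {
  if (!is.finite(value)) .stopf("reward must be finite")
  structure(list(value = value), class = "reward_signal")
}

#' Apply a reward to eligibility traces (R-STDP weight update)
#'
#' Discrete form of the reward-modulated rule \eqn{\dot w = e\,r}: applied
#' once per decision window,
#' \deqn{w \leftarrow \mathrm{clip}(w + \eta\, e\, r,\ -1,\ 1).}
#'
#' @param syn a [synapse_matrix()] whose traces are current.
#' @param reward a [reward_signal()] or a plain numeric scalar.
#' @return the updated [synapse_matrix()].
#' @export
apply_reward <- function(syn, reward) {
  r <- if (inherits(reward, "reward_signal")) reward$value else reward
  if (!is.finite(r)) .stopf("reward must be finite")
  syn$weights <- .clip(syn$weights + syn$learning_rate * syn$traces * r)
  syn
}

# In-place R-STDP update restricted to the active input columns of a tonic
# window; equivalent to filling the full trace matrix and calling
# apply_reward() (tested), but touches only the active columns.
.rstdp_update <- function(syn, trace_vec, active_idx, reward) {
  if (!length(active_idx) || reward == 0) return(syn)
  syn$weights[, active_idx] <- .clip(
    syn$weights[, active_idx, drop = FALSE] +
      syn$learning_rate * reward * trace_vec
  )
  syn
}

# Rows of one output population within a partition.
.pop_rows <- function(partition, label) {
  k <- match(label, partition$labels)
  J <- partition$neurons_per_population
  ((k - 1L) * J + 1L):(k * J)
}

# Eligibility trace of a nominally stimulated assembly: the per-neuron trace
# a neuron firing at a typical suprathreshold rate (every 3rd step) would
# accumulate. Used when an explored/expressed population was silent in the
# free-running pass: the exploration signal is taken to stimulate the chosen
# assembly, giving its synapses a standard eligibility.
.reference_trace <- function(T_len, tau_e, dt, params) {
  raster <- matrix(0L, 1L, T_len)
  raster[1L, seq(3L, T_len, by = 3L)] <- 1L
  .tonic_trace_vec(raster, tau_e, dt, params)[1L]
}

# Winner-take-all gated trace: lateral inhibition suppresses the activity
# (and hence the eligibility) of every population except the acting one, so
# the reward-modulated update credits only the assembly whose action was
# expressed. The assembly's eligibility is normalised to the stimulation
# trace magnitude (preserving the within-population structure); without
# this, an already-dominant assembly's high firing rate would give it far
# larger updates than explored competitors, regardless of reward. A silent
# acting assembly receives the stimulation trace outright.
.gated_trace <- function(post, partition, label, tau_e, dt, params) {
  rows <- .pop_rows(partition, label)
  ref <- .reference_trace(ncol(post), tau_e, dt, params)
  sub <- post[rows, , drop = FALSE]
  if (sum(sub) == 0L) {
    tv <- rep(ref, length(rows))
  } else {
    tv <- .tonic_trace_vec(sub, tau_e, dt, params)
    m <- mean(tv)
    if (m > 0) tv <- tv * (ref / m)
  }
  list(rows = rows, trace = tv)
}

# R-STDP update of one population's synapses from the active inputs, with
# eligibility-gated synaptic decay: eligible synapses relax toward zero at
# rate `decay` per update, so weights that are not consistently reinforced
# revert instead of accumulating a random walk, while consistently rewarded
# synapses equilibrate at large magnitude.
.rstdp_update_pop <- function(syn, rows, trace_vec, active_idx, reward,
                              decay = 0.15) {
  if (!length(active_idx)) return(syn)
  w <- syn$weights[rows, active_idx, drop = FALSE]
  syn$weights[rows, active_idx] <- .clip(
    w + syn$learning_rate * (reward * trace_vec - decay * w)
  )
  syn
}

#' Unmodulated pairwise STDP update
#'
#' Applies the raw STDP window to nearest-neighbour pre/post spike pairs over
#' a pair of rasters and changes the weights directly (no reward, no
#' eligibility decay): \eqn{w \leftarrow \mathrm{clip}(w + \eta \sum STDP(\Delta t))}.
#'
#' @param syn a [synapse_matrix()].
#' @param pre_raster binary raster (inputs x T).
#' @param post_raster binary raster (outputs x T), same length.
#' @param dt step length (ms).
#' @param params an [stdp_params()].
#' @return the updated [synapse_matrix()].
#' @export
unsupervised_stdp_update <- function(syn, pre_raster, post_raster, dt = 1,
                                     params = stdp_params()) {
  if (ncol(pre_raster) != ncol(post_raster)) {
    .stopf("pre and post rasters must cover the same steps")
  }
  delta <- matrix(0, nrow(post_raster), nrow(pre_raster))
  last_pre <- rep(NA_real_, nrow(pre_raster))
  last_post <- rep(NA_real_, nrow(post_raster))
  for (t in seq_len(ncol(pre_raster))) {
    t_now <- t * dt
    post_idx <- which(post_raster[, t] > 0)
    if (length(post_idx)) {
      dtp <- last_pre - t_now
      has <- !is.na(dtp)
      if (any(has)) {
        v <- numeric(length(dtp))
        v[has] <- stdp_window(dtp[has], params)
        delta[post_idx, ] <- delta[post_idx, , drop = FALSE] +
          matrix(v, length(post_idx), length(v), byrow = TRUE)
      }
    }
    pre_idx <- which(pre_raster[, t] > 0)
    if (length(pre_idx)) {
      dtm <- t_now - last_post
      has <- !is.na(dtm)
      if (any(has)) {
        v <- numeric(length(dtm))
        v[has] <- stdp_window(dtm[has], params)
        delta[, pre_idx] <- delta[, pre_idx, drop = FALSE] +
          matrix(v, length(v), length(pre_idx))
      }
    }
    last_pre[pre_idx] <- t_now
    last_post[post_idx] <- t_now
  }
  syn$weights <- .clip(syn$weights + syn$learning_rate * delta)
  syn
}
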