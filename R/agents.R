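#' Decision network of one agent
#'
#' A two-layer spiking network mapping a population-coded observation
#' (588 input channels) to 5 action populations of 6 LIF neurons each
#' (up, down, left, right, stay). Weights are drawn uniformly from
#' [0, 0.3] with the current RNG state and are trained by R-STDP.
#'
#' @param seed optional seed for weight initialisation.
#' @param window decision window length T (steps).
#' @param gain input gain; together with the background bias it places the
#'   drive of a typical learned stimulus in the monotone range of the
#'   spike-count response, below the count ceiling.
#' @param inhibition_strength lateral-inhibition strength at decode time.
#' @param neuron a [neuron_params()].
#' @param stdp an [stdp_params()].
#' @param tau_e eligibility trace time constant (ms).
#' @param learning_rate R-STDP learning rate.
#' @param bias_range range of the fixed per-neuron background bias currents:
#'   each population's 6 neurons receive evenly spaced levels across this
#'   range, which keeps every population responsive and dithers the
#'   spike-count quantisation so counts read out the synaptic drive
#'   faithfully.
#' @return an object of class `decision_network`.
#' @export
decision_network <- function(seed = NULL, window = 50L, gain = 20,
                             inhibition_strength = 0.1,
                             neuron = neuron_params(), stdp = stdp_params(),
                             tau_e = 5, learning_rate = 0.1,
                             bias_range = c(25, 65)) {
  if (!is.null(seed)) set.seed(seed)
  structure(
    list(
      syn = synapse_matrix(5L * 6L, N_OBS_CHANNELS, init_range = c(0, 0.05),
                           tau_e = tau_e, learning_rate = learning_rate),
      partition = population_partition(ACTIONS, 6L),
      window = as.integer(window),
      gain = gain,
      bias = .bias_levels(5L, 6L, bias_range),
      neuron = neuron,
      stdp = stdp,
      inhibition = lateral_inhibition_config(inhibition_strength)
    ),
    class = "decision_network"
  )
}

#' @export
print.decision_network <- function(x, ...) {
  cat(sprintf("<decision_network> 588 -> 5x6, T=%d, gain=%g, w in [%.3f, %.3f]\n",
              x$window, x$gain, min(x$syn$weights), max(x$syn$weights)))
  invisible(x)
}

# One forward window over a tonic stimulus for any of the package's
# two-layer networks; returns the output raster.
.net_forward <- function(net, active_idx) {
  .tonic_forward(net$syn$weights, active_idx, net$window, net$neuron,
                 net$gain, net$bias %||% 0)
}

.net_decode <- function(net, post) {
  counts <- population_counts(post, net$partition)
  .decode_counts(counts, net$partition, net$inhibition)
}

# Forward pass + decode + epsilon-greedy exploration; keeps the post raster
# and active channels for the plasticity update.
.act_full <- function(net, obs, epsilon = 0) {
  active <- which(encode_observation(obs) == 1L)
  post <- .net_forward(net, active)
  net_action <- .net_decode(net, post)
  executed <- net_action
  if (is.na(executed)) {
    executed <- ACTIONS[sample.int(5L, 1L)] # silent network: random fallback
  }
  if (epsilon > 0 && runif(1) < epsilon) {
    executed <- ACTIONS[sample.int(5L, 1L)]
  }
  list(action = executed, net_action = net_action, post = post,
       active = active)
}

#' Choose an action from an observation
#'
#' Encodes the observation, runs one decision window through the network and
#' decodes the winning action population (with lateral inhibition). With
#' `explore = TRUE` an epsilon-greedy uniform random action may be
#' substituted. A silent network (no output spikes) falls back to a uniform
#' random action.
#'
#' @param net a [decision_network()].
#' @param obs a `grid_observation` from [observe()].
#' @param explore enable epsilon-greedy exploration?
#' @param epsilon exploration probability (used when `explore` is TRUE).
#' @return an action label.
#' @export
act <- function(net, obs, explore = FALSE, epsilon = 0) {
  .act_full(net, obs, if (explore) epsilon else 0)$action
}

#' Training configuration
#'
#' @param episodes number of training episodes.
#' @param exploration_epsilon initial epsilon-greedy exploration rate.
#' @param epsilon_min floor of the exploration rate.
#' @param epsilon_decay_frac fraction of episodes over which epsilon decays
#'   linearly from its initial value to the floor.
#' @param rng_seed master seed; all environment, initialisation and
#'   exploration randomness fans out from it via [child_seed()].
#' @param step_cap maximum steps per episode.
#' @return an object of class `training_config`.
#' @export
training_config <- function(episodes = 300L, exploration_epsilon = 1.0,
                            epsilon_min = 0.05, epsilon_decay_frac = 0.5,
                            rng_seed = 1L, step_cap = 30L) {
  if (episodes < 0L) .stopf("episodes must be >= 0")
  structure(list(episodes = as.integer(episodes),
                 exploration_epsilon = exploration_epsilon,
                 epsilon_min = epsilon_min,
                 epsilon_decay_frac = epsilon_decay_frac,
                 rng_seed = as.integer(rng_seed),
                 step_cap = as.integer(step_cap)),
            class = "training_config")
}

.epsilon_at <- function(cfg, episode) {
  horizon <- max(1, cfg$epsilon_decay_frac * cfg$episodes)
  max(cfg$epsilon_min,
      cfg$exploration_epsilon -
        (cfg$exploration_epsilon - cfg$epsilon_min) * (episode - 1) / horizon)
}

#' Train a decision network for one behaviour style with R-STDP
#'
#' Training runs in two stages, mirroring the staged environments of
#' [train_tom()]:
#' \itemize{
#'   \item Stage 1 (the first `solo_frac` of the episodes): the learner is
#'     alone in randomised wall-free worlds and acquires goal pursuit. The
#'     executed action's population carries the window's eligibility trace
#'     (lateral inhibition suppresses the competing assemblies'
#'     eligibility; the trace is normalised to a standard stimulation
#'     magnitude) and the dopamine signal converts it into a weight change
#'     \eqn{\Delta w = \eta(e\,\delta - \lambda w)}, clipped to [-1, 1].
#'     The dopamine \eqn{\delta} is the reward prediction error (reward
#'     minus a running expectation); competing populations receive the
#'     opposite-signed update in proportion to their activity share (the
#'     plasticity face of winner-take-all competition). Eligible synapses
#'     decay toward zero at rate \eqn{\lambda}, so weights that are not
#'     consistently reinforced revert instead of random-walking.
#'   \item Stage 2 (the remainder): worlds gain a wall segment and a
#'     scripted reckless companion, and the style-specific penalties and
#'     wall terms of [compute_reward()] shape avoidance behaviour on top of
#'     the established navigation: only the executed population is updated
#'     (at a reduced, annealed learning rate), so penalties depress the
#'     specific action-context associations that caused them while
#'     ordinary progress maintains the navigation weights.
#' }
#' Learning rates anneal exponentially within each stage, freezing the
#' solution and shrinking residual update noise. Without the staging, the
#' heavy penalties of the experienced and cautious styles dominate the
#' learning signal before goal pursuit exists, and training collapses into
#' a never-moving policy.
#'
#' @param policy behaviour style to train (`"reckless"`, `"experienced"`,
#'   `"cautious"`); selects the reward function of [compute_reward()].
#' @param cfg a [training_config()].
#' @param net optional starting [decision_network()]; by default a fresh one
#'   is initialised from `child_seed(cfg$rng_seed, 1)`.
#' @param window,gain network construction parameters (used when `net` is
#'   NULL).
#' @param weight_decay eligibility-gated synaptic decay rate \eqn{\lambda}.
#' @param baseline_rate update rate of the running reward expectation that
#'   the dopamine signal is measured against.
#' @param solo_frac fraction of episodes in the solo navigation stage.
#' @param stage2_rate learning rate at the start of the social stage.
#' @return the trained network; the per-episode learning curve is attached
#'   as `attr(net, "curve")` (episode, total reward, steps, epsilon).
#' @export
train_decision_module <- function(policy, cfg = training_config(),
                                  net = NULL, window = 50L, gain = 20,
                                  weight_decay = 0.15, baseline_rate = 0.1,
                                  solo_frac = 0.6, stage2_rate = 0.05) {
  if (!(policy %in% STYLES)) .stopf("unknown policy '%s'", policy)
  if (is.null(net)) {
    net <- decision_network(seed = child_seed(cfg$rng_seed, 1L),
                            window = window, gain = gain)
  }
  curve <- data.frame(episode = integer(), reward = numeric(),
                      steps = integer(), epsilon = numeric())
  eta0 <- net$syn$learning_rate
  r_bar <- 0 # running reward expectation; dopamine = reward - expectation
  n_solo <- round(solo_frac * cfg$episodes)
  for (ep in seq_len(cfg$episodes)) {
    solo <- ep <= n_solo
    if (solo) {
      eps <- .epsilon_at(cfg, ep / max(solo_frac, 1e-9))
      net$syn$learning_rate <- eta0 * .anneal_at(ep, n_solo)
      world <- generate_environment(child_seed(cfg$rng_seed, 100L + ep),
                                    n_agents = 1L, with_walls = FALSE,
                                    policies = policy)
    } else {
      eps <- cfg$epsilon_min
      fd2 <- (ep - n_solo) / max(cfg$episodes - n_solo, 1L)
      net$syn$learning_rate <- stage2_rate * 0.1^fd2
      world <- generate_environment(child_seed(cfg$rng_seed, 100L + ep),
                                    n_agents = 2L, with_walls = TRUE,
                                    policies = c(policy, "reckless"))
    }
    total <- 0
    steps <- 0L
    while (!world$agents[[1]]$done && steps < cfg$step_cap) {
      af <- .act_full(net, observe(world, 1L), epsilon = eps)
      actions <- list("1" = af$action)
      if (!solo && !world$agents[[2]]$done) {
        actions[["2"]] <- scripted_policy("reckless", observe(world, 2L))
      }
      res <- step_world(world, actions)
      world <- res$world
      r <- compute_reward(policy, res$transitions[["1"]])
      # dopamine: reward prediction error against the running expectation,
      # normalised into [-1, 1] (large penalties saturate instead of
      # destabilising the expectation)
      dopamine <- .clip(r - r_bar)
      r_bar <- r_bar + baseline_rate * (.clip(r) - r_bar)
      if (solo) {
        net$syn <- .competitive_rstdp(net, af$post, af$action, af$active,
                                      dopamine, weight_decay)
      } else {
        gt <- .gated_trace(af$post, net$partition, af$action,
                           net$syn$tau_e, net$neuron$dt, net$stdp)
        net$syn <- .rstdp_update_pop(net$syn, gt$rows, gt$trace, af$active,
                                     dopamine, decay = 0)
      }
      total <- total + r
      steps <- steps + 1L
    }
    curve <- rbind(curve, data.frame(episode = ep, reward = total,
                                     steps = steps, epsilon = eps))
  }
  net$syn$learning_rate <- eta0
  attr(net, "curve") <- curve
  attr(net, "policy") <- policy
  net
}

# Learning-rate annealing factor: full rate for the first 40% of training,
# then exponential decay to 1% at the end.
.anneal_at <- function(episode, episodes) {
  fd <- episode / max(episodes, 1)
  if (fd <= 0.4) 1 else 0.01^((fd - 0.4) / 0.6)
}

# Mistake-driven, teacher-corrected update for the supervised ToM
# networks: dopamine responds to surprise, so nothing changes while the
# expressed judgment matches the outcome by a comfortable activity margin;
# on a mistake (or a too-narrow win), the wrongly expressed population is
# depressed and the true population is driven by a corrective stimulation
# trace, both on the active input channels. This keeps a heavily
# imbalanced outcome distribution (mostly-safe states, say) from burying
# the minority class under majority reinforcement, and the margin
# requirement keeps rare decisive features from equilibrating at a
# hair-thin advantage that any context variation would erase.
.perceptron_rstdp <- function(net, post, expressed, truth, active_idx,
                              margin = 5) {
  counts <- population_counts(post, net$partition)
  rivals <- counts[names(counts) != truth]
  lead <- counts[[truth]] - max(rivals)
  if (!is.na(expressed) && expressed == truth && lead >= margin) {
    return(net$syn)
  }
  # the competitor to depress: the wrongly expressed population, or -- on a
  # below-margin win -- the strongest rival
  loser <- if (!is.na(expressed) && expressed != truth) {
    expressed
  } else {
    names(rivals)[which.max(rivals)]
  }
  syn <- net$syn
  ref <- .reference_trace(ncol(post), syn$tau_e, net$neuron$dt, net$stdp)
  J <- net$partition$neurons_per_population
  gt <- .gated_trace(post, net$partition, loser,
                     syn$tau_e, net$neuron$dt, net$stdp)
  syn <- .rstdp_update_pop(syn, gt$rows, gt$trace, active_idx, -1, decay = 0)
  syn <- .rstdp_update_pop(syn, .pop_rows(net$partition, truth),
                           rep(ref, J), active_idx, 1, decay = 0)
  syn
}

# One reward-modulated competitive update of a network's synapses: the
# expressed population receives dopamine x its (normalised, gated)
# eligibility trace with eligibility-gated decay; every competing
# population receives the opposite-signed update weighted by its share of
# the window's activity (the plasticity face of winner-take-all
# competition).
.competitive_rstdp <- function(net, post, label, active_idx, dopamine,
                               weight_decay = 0.15) {
  syn <- net$syn
  gt <- .gated_trace(post, net$partition, label,
                     syn$tau_e, net$neuron$dt, net$stdp)
  syn <- .rstdp_update_pop(syn, gt$rows, gt$trace, active_idx, dopamine,
                           decay = weight_decay)
  counts <- population_counts(post, net$partition)
  share <- counts / max(sum(counts), 1)
  ref <- .reference_trace(ncol(post), syn$tau_e, net$neuron$dt, net$stdp)
  J <- net$partition$neurons_per_population
  for (lab in net$partition$labels) {
    if (lab == label) next
    syn <- .rstdp_update_pop(syn, .pop_rows(net$partition, lab),
                             rep(ref, J), active_idx,
                             -dopamine * share[[lab]], decay = 0)
  }
  syn
}

#' Deterministic scripted policies (oracle agents)
#'
#' Hand-written counterparts of the three behaviour styles, used as
#' deterministic opponents during training and as oracles in tests:
#' \itemize{
#'   \item reckless: greedy step along the shortest path (BFS over walls) to
#'     the goal, ignoring other agents;
#'   \item experienced: the same, but never steps onto a cell currently
#'     occupied by a visible agent (falls back to the best non-colliding
#'     action, or stays);
#'   \item cautious: maximises goal progress plus wall-distance gain and
#'     strongly avoids candidate cells within one cell of a wall.
#' }
#' Ties are broken by the fixed action order up, down, left, right, stay.
#'
#' @param style behaviour style.
#' @param obs a `grid_observation`.
#' @return an action label.
#' @export
scripted_policy <- function(style, obs) {
  if (!(style %in% STYLES)) .stopf("unknown style '%s'", style)
  size <- GRID_SIZE
  dist <- obs$goal_dist
  if (is.null(dist)) dist <- bfs_distances(obs$walls, obs$goal, size)
  is_wall <- function(cell) {
    !is.null(obs$walls) && nrow(obs$walls) &&
      any(obs$walls[, 1] == cell[1] & obs$walls[, 2] == cell[2])
  }
  occupied <- function(cell) {
    any(vapply(obs$visible_agents, function(p) all(p == cell), TRUE))
  }
  cand <- lapply(ACTIONS, function(a) {
    target <- obs$self_position + ACTION_DELTAS[a, ]
    if (any(target < 1) || any(target > size) || is_wall(target)) {
      obs$self_position # blocked: acts like stay
    } else {
      target
    }
  })
  names(cand) <- ACTIONS
  d_cand <- vapply(cand, function(p) dist[p[1], p[2]], numeric(1))
  pick <- function(score) ACTIONS[which.max(score)]
  switch(style,
    reckless = pick(-d_cand),
    experienced = {
      score <- -d_cand
      bad <- vapply(cand, occupied, TRUE)
      score[bad] <- -Inf
      if (all(!is.finite(score))) "stay" else pick(score)
    },
    cautious = {
      dw_prev <- .wall_distance(obs$walls, obs$self_position)
      d_prev <- dist[obs$self_position[1], obs$self_position[2]]
      score <- vapply(ACTIONS, function(a) {
        p <- cand[[a]]
        dw <- .wall_distance(obs$walls, p)
        s <- (d_prev - dist[p[1], p[2]]) / max(d_prev, 1)
        if (is.finite(dw_prev) && dw_prev > 0) {
          s <- s + (min(dw, 10) - min(dw_prev, 10)) / dw_prev
        }
        if (is.finite(dw) && dw <= 1) s <- s - 10
        if (occupied(p)) s <- s - 10
        s
      }, numeric(1))
      pick(score)
    }
  )
}

#' Train the three style policies
#'
#' Convenience wrapper running [train_decision_module()] for the reckless,
#' experienced and cautious styles with per-style child seeds.
#'
#' @param cfg a [training_config()]; `cfg$rng_seed` fans out into one seed
#'   per style.
#' @param window,gain network construction parameters.
#' @return named list of trained [decision_network()]s.
#' @export
train_policies <- function(cfg = training_config(episodes = 900L),
                           window = 50L, gain = 20) {
  nets <- lapply(seq_along(STYLES), function(i) {
    style_cfg <- cfg
    style_cfg$rng_seed <- child_seed(cfg$rng_seed, 10L + i)
    train_decision_module(STYLES[i], style_cfg, window = window, gain = gain)
  })
  names(nets) <- STYLES
  nets
}
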