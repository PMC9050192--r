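#' Fixed perspective-taking network
#'
#' The perspective-taking stage maps the pair (self-relevant stimuli,
#' other-relevant stimuli) onto an inference of the other agent's
#' observation. Its weights are fixed gating weights and never change:
#' other-relevant channels pass through, and self-relevant agent channels
#' are suppressed wherever the other agent's visibility mask is false
#' (self-perspective inhibition). The object carries no trainable state.
#'
#' @return an object of class `perspective_network`.
#' @export
perspective_network <- function() {
  structure(list(frozen = TRUE,
                 n_in = 2L * N_OBS_CHANNELS, n_out = N_OBS_CHANNELS),
            class = "perspective_network")
}

#' Bundle of ToM networks
#'
#' The four ToM submodules of the bystander: the fixed perspective-taking
#' gate, the policy-inference network ((6+8) inputs -> 3 style populations),
#' the action-prediction network (3 style-conditioned copies of the 588
#' observation channels -> 5 action populations) and the state-evaluation
#' network (588 egocentric channels -> safe/unsafe populations). All
#' trainable weights start uniform in [0, 0.3] and stay in [-1, 1].
#'
#' @param seed optional seed for weight initialisation.
#' @param window decision window length T.
#' @param gain input gain of the observation-driven networks.
#' @param policy_gain input gain of the small (6+8)-input policy-inference
#'   network; larger because only a handful of channels are active at once.
#' @param inhibition_strength lateral-inhibition strength at decode time.
#' @param neuron,stdp,tau_e,learning_rate shared neuron/plasticity settings.
#' @return an object of class `tom_networks`.
#' @export
tom_networks <- function(seed = NULL, window = 50L, gain = 20,
                         policy_gain = 60, inhibition_strength = 0.1,
                         neuron = neuron_params(), stdp = stdp_params(),
                         tau_e = 5, learning_rate = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  base <- list(window = as.integer(window), neuron = neuron, stdp = stdp,
               inhibition = lateral_inhibition_config(inhibition_strength))
  mknet <- function(n_out, n_in, labels, J, g) {
    c(base, list(
      syn = synapse_matrix(n_out, n_in, init_range = c(0, 0.05),
                           tau_e = tau_e, learning_rate = learning_rate),
      partition = population_partition(labels, J),
      gain = g,
      bias = .bias_levels(length(labels), J)
    ))
  }
  policy <- mknet(3L * 6L, 14L, STYLES, 6L, policy_gain)
  policy$syn$weights[, 1:6] <- .style_persistence_weights()
  structure(
    list(
      perspective = perspective_network(),
      policy = policy,
      action = mknet(5L * 6L, 3L * N_OBS_CHANNELS, ACTIONS, 6L, gain),
      safety = mknet(2L * 6L, N_OBS_CHANNELS, SAFETY_LABELS, 6L, gain)
    ),
    class = "tom_networks"
  )
}

# Fixed evidence-persistence weights of the policy-inference recurrence:
# the two input channels carrying the previous estimate of style k excite
# style k's own population with a moderate fixed weight, so the estimate
# carries over between steps and the per-step behaviour bits accumulate
# into it rather than having to decide alone. Like the perspective gating,
# these weights are structural and are re-pinned after every plastic
# update.
.style_persistence_weights <- function(strength = 0.25) {
  w <- matrix(0, 3L * 6L, 6L)
  for (k in 1:3) {
    w[((k - 1L) * 6L + 1L):(k * 6L), ((k - 1L) * 2L + 1L):(k * 2L)] <- strength
  }
  w
}

#' @export
print.tom_networks <- function(x, ...) {
  cat(sprintf(paste0("<tom_networks> T=%d; policy 14->3x6, action 1764->5x6, ",
                     "safety 588->2x6, perspective fixed\n"), x$policy$window))
  invisible(x)
}

#' Infer another agent's observation (perspective taking)
#'
#' Builds the observation the other agent would have, from the observer's
#' own knowledge: walls and the other's goal are globally known; the agents
#' the observer knows about (its visible agents plus itself) are passed
#' through the other agent's visibility mask, so an agent occluded from the
#' other's viewpoint is absent from the inference even if the observer sees
#' it. This realises self-perspective inhibition as fixed gating.
#'
#' @param net a [perspective_network()] (fixed; present for interface
#'   symmetry).
#' @param self_obs the observer's own `grid_observation`.
#' @param other_id id of the observed agent, which must be visible in
#'   `self_obs`.
#' @param world the `gridworld` (supplies walls and the other's goal).
#' @return the inferred `grid_observation` of the other agent, or `NULL` if
#'   the other agent is not visible to the observer (callers fall back to
#'   their cached estimate).
#' @export
infer_other_observation <- function(net, self_obs, other_id, world) {
  other_pos <- self_obs$visible_agents[[as.character(other_id)]]
  if (is.null(other_pos)) return(NULL)
  vis <- visible_cells(world, other_pos)
  known <- self_obs$visible_agents
  known[[as.character(self_obs$self_id)]] <- self_obs$self_position
  known[[as.character(other_id)]] <- NULL
  keep <- vapply(known, function(p) vis[p[1], p[2]], TRUE)
  structure(
    list(walls = world$walls,
         goal = world$agents[[other_id]]$goal,
         self_position = other_pos,
         self_id = as.integer(other_id),
         visible_agents = known[keep],
         visibility = vis,
         goal_dist = if (!is.null(world$goal_dists)) {
           world$goal_dists[[other_id]]
         } else {
           NULL
         }),
    class = "grid_observation"
  )
}

#' Behaviour summary bits for policy inference
#'
#' The (6+8) policy-inference input consists of the previous style estimate
#' (3 populations of 2 neurons) and 8 binary summary bits derived from the
#' difference between the observed agent's configuration at t-1 and t plus
#' its last safety status: moved toward goal, deviated from the
#' shortest-path step (the signature of avoidance behaviour), moved away
#' from the nearest wall, is within one cell of a wall, avoided a
#' goal-ward cell occupied by another agent, stayed in place, last judged
#' unsafe, last judged safe.
#'
#' @param prev_pos the agent's cell at t-1 (`NULL` on the first step).
#' @param cur_pos the agent's cell at t.
#' @param goal the agent's goal cell.
#' @param walls wall matrix or `NULL`.
#' @param occupied list of cells occupied by other agents at t-1.
#' @param last_safety `"safe"`, `"unsafe"` or `NA`.
#' @return integer vector of 8 bits.
#' @export
policy_bits <- function(prev_pos, cur_pos, goal, walls,
                        occupied = list(), last_safety = NA) {
  bits <- integer(8L)
  if (!is.null(prev_pos)) {
    dp_prev <- .euclid(prev_pos, goal)
    dp_now <- .euclid(cur_pos, goal)
    bits[1] <- as.integer(dp_now < dp_prev)
    # deviation from the shortest path: the step taken was not one of the
    # geodesically optimal moves from the previous cell
    gd <- bfs_distances(walls, goal)
    best <- Inf
    greedy <- list()
    for (a in 1:4) {
      p <- prev_pos + ACTION_DELTAS[a, ]
      if (any(p < 1) || any(p > GRID_SIZE)) next
      d <- gd[p[1], p[2]]
      if (!is.finite(d)) next
      if (d < best - 1e-9) {
        best <- d
        greedy <- list(p)
      } else if (d < best + 1e-9) {
        greedy <- c(greedy, list(p))
      }
    }
    on_greedy <- any(vapply(greedy, function(p) all(p == cur_pos), TRUE))
    bits[2] <- as.integer(length(greedy) > 0 && !on_greedy)
    dw_prev <- .wall_distance(walls, prev_pos)
    dw_now <- .wall_distance(walls, cur_pos)
    bits[3] <- as.integer(is.finite(dw_prev) && dw_now > dw_prev)
    bits[4] <- as.integer(is.finite(dw_now) && dw_now <= 1)
    # Greedy goal-ward neighbour of the previous cell; if it was occupied
    # and the agent did not enter it, the agent avoided a collision.
    if (length(occupied)) {
      nb <- lapply(ACTIONS[1:4], function(a) prev_pos + ACTION_DELTAS[a, ])
      ok <- vapply(nb, function(p) {
        all(p >= 1) && all(p <= GRID_SIZE) &&
          !(!is.null(walls) && nrow(walls) &&
              any(walls[, 1] == p[1] & walls[, 2] == p[2]))
      }, TRUE)
      if (any(ok)) {
        dists <- vapply(nb, function(p) .euclid(p, goal), numeric(1))
        dists[!ok] <- Inf
        greedy <- nb[[which.min(dists)]]
        occ <- any(vapply(occupied, function(p) all(p == greedy), TRUE))
        bits[5] <- as.integer(occ && !all(cur_pos == greedy))
      }
    }
    bits[6] <- as.integer(all(cur_pos == prev_pos))
  }
  if (!is.na(last_safety)) {
    bits[7] <- as.integer(last_safety == "unsafe")
    bits[8] <- as.integer(last_safety == "safe")
  }
  bits
}

# 14-channel policy-inference input: previous style estimate (pairs of
# neurons per style) + the 8 summary bits.
.encode_policy_input <- function(prev_style, bits) {
  x <- integer(14L)
  if (!is.null(prev_style) && !is.na(prev_style)) {
    k <- match(prev_style, STYLES)
    x[((k - 1L) * 2L + 1L):(k * 2L)] <- 1L
  }
  x[7:14] <- bits
  x
}

#' Infer the observed agent's behaviour style
#'
#' Forward pass of the policy-inference network over the (6+8) input
#' (previous estimate + behaviour summary bits), decoded over the three
#' style populations. A silent network keeps the previous estimate.
#'
#' @param net the `policy` element of a [tom_networks()] bundle.
#' @param prev_estimate previous style label or `NA`.
#' @param bits the 8 [policy_bits()].
#' @return the style label (or `NA` if the network is silent and there is
#'   no previous estimate).
#' @export
infer_behavior_style <- function(net, prev_estimate, bits) {
  active <- which(.encode_policy_input(prev_estimate, bits) == 1L)
  post <- .net_forward(net, active)
  est <- .net_decode(net, post)
  if (is.na(est)) prev_estimate else est
}

.infer_style_full <- function(net, prev_estimate, bits) {
  active <- which(.encode_policy_input(prev_estimate, bits) == 1L)
  post <- .net_forward(net, active)
  est <- .net_decode(net, post)
  list(style = if (is.na(est)) prev_estimate else est,
       raw = est, post = post, active = active)
}

#' Behaviour-style prediction reward
#'
#' \eqn{e_{bs} = -\gamma\,[\hat{bs} \ne bs] + \beta}: with the standard
#' constants gamma = 2, beta = 1 a correct style prediction earns +1 and an
#' incorrect one -1, so the reward always lies in [-1, 1]. An `NA`
#' prediction counts as incorrect.
#'
#' @param predicted predicted style label (may be `NA`).
#' @param actual true style label.
#' @param gamma,beta reward constants.
#' @return scalar reward.
#' @export
style_reward <- function(predicted, actual, gamma = 2, beta = 1) {
  mismatch <- is.na(predicted) || predicted != actual
  -as.numeric(mismatch) * gamma + beta
}

# Action-prediction input: the 588-channel encoding of the inferred
# observation replicated into the block of the inferred style; an unknown
# style activates all three blocks (uniform style prior).
.action_pred_active <- function(obs_hat, style) {
  enc <- which(encode_observation(obs_hat) == 1L)
  blocks <- if (is.null(style) || is.na(style)) 1:3 else match(style, STYLES)
  as.integer(unlist(lapply(blocks, function(b) (b - 1L) * N_OBS_CHANNELS + enc)))
}

#' Predict the observed agent's next action
#'
#' Encodes the inferred observation into the style-conditioned input block
#' of the action-prediction network and decodes over the five action
#' populations (with lateral inhibition). A silent network predicts
#' `"stay"`; an unknown style activates all three style blocks (uniform
#' prior).
#'
#' @param net the `action` element of a [tom_networks()] bundle.
#' @param other_obs_hat the inferred `grid_observation` of the observed
#'   agent.
#' @param style the inferred behaviour style (may be `NA`).
#' @return an action label.
#' @export
predict_other_action <- function(net, other_obs_hat, style) {
  active <- .action_pred_active(other_obs_hat, style)
  est <- .net_decode(net, .net_forward(net, active))
  if (is.na(est)) "stay" else est
}

#' Apply the movement rule to a single agent
#'
#' Deterministic next cell under the gridworld movement rules, all other
#' agents staying: a move into a wall or off the grid leaves the agent in
#' place. Equals [step_world()] restricted to one agent.
#'
#' @param world a `gridworld`.
#' @param position current cell.
#' @param action action label.
#' @return the next cell `c(row, col)`.
#' @export
predict_next_state <- function(world, position, action) {
  .move_result(world, position, action)$cell
}

.move_result <- function(world, position, action) {
  if (any(position < 1) || any(position > world$size)) {
    .stopf("position (%s) is off-grid", paste(position, collapse = ","))
  }
  target <- position + ACTION_DELTAS[action, ]
  blocked <- any(target < 1) || any(target > world$size) ||
    (!is.null(world$walls) && nrow(world$walls) &&
       any(world$walls[, 1] == target[1] & world$walls[, 2] == target[2]))
  if (blocked) list(cell = position, blocked = TRUE)
  else list(cell = target, blocked = FALSE)
}

#' Hypothesised next-state description for safety evaluation
#'
#' @param walls wall matrix or `NULL`.
#' @param focus the observed agent's (predicted) next cell.
#' @param others named list of the remaining agents' (predicted) cells.
#' @param blocked was the (predicted) move blocked by a wall or the
#'   boundary?
#' @param others_now named list of the remaining agents' current cells.
#' @param origin the observed agent's current cell.
#' @return an object of class `predicted_state`.
#' @export
predicted_state <- function(walls, focus, others = list(), blocked = FALSE,
                            others_now = list(), origin = NULL) {
  structure(list(walls = walls, focus = focus, others = others,
                 blocked = blocked, others_now = others_now,
                 origin = origin),
            class = "predicted_state")
}

#' Evaluate the safety of a (predicted) agent state
#'
#' Encodes the state egocentrically around the observed agent
#' ([encode_relative_state()]) and decodes the safe/unsafe populations of
#' the state-evaluation network. A silent network returns `"safe"`
#' (non-intervention default).
#'
#' @param net the `safety` element of a [tom_networks()] bundle.
#' @param state a [predicted_state()].
#' @return `"safe"` or `"unsafe"`.
#' @export
evaluate_safety <- function(net, state) {
  active <- which(encode_relative_state(state$walls, state$focus,
                                        state$others, state$blocked,
                                        state$others_now, state$origin) == 1L)
  est <- .net_decode(net, .net_forward(net, active))
  if (is.na(est)) "safe" else est
}

# The actual collision predicate used as the state-evaluation teacher: the
# focal agent's move is blocked, its next cell coincides with another
# agent's next cell, or it exchanges cells with another agent (a swap).
.collision_predicate <- function(state) {
  if (state$blocked) return(TRUE)
  if (any(vapply(state$others, function(p) all(p == state$focus), TRUE))) {
    return(TRUE)
  }
  if (!is.null(state$origin) && length(state$others_now)) {
    for (id in names(state$others)) {
      now <- state$others_now[[id]]
      if (is.null(now)) next
      if (all(state$others[[id]] == state$origin) &&
          all(now == state$focus)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Initialise the bystander's running ToM state
#'
#' Tracks, per pedestrian, the previous position, the current style and
#' safety estimates, and the previous occupancy snapshot used by
#' [policy_bits()].
#'
#' @param world a `gridworld`.
#' @param bystander_id id of the ToM-equipped agent.
#' @return an object of class `tom_state`.
#' @export
tom_state_init <- function(world, bystander_id = 1L) {
  peds <- setdiff(seq_along(world$agents), bystander_id)
  per <- lapply(peds, function(k) {
    list(prev_pos = NULL, style = NA_character_, safety = NA_character_)
  })
  names(per) <- as.character(peds)
  structure(list(bystander_id = as.integer(bystander_id), per = per,
                 prev_occupied = NULL),
            class = "tom_state")
}

# Current positions of all active agents except `exclude`.
.active_positions <- function(world, exclude = integer()) {
  out <- list()
  for (a in world$agents) {
    if (a$done || a$id %in% exclude) next
    out[[as.character(a$id)]] <- a$position
  }
  out
}

#' One bystander step: run the ToM chain and decide whether to help
#'
#' For every visible active pedestrian (ascending id) the bystander runs the
#' full chain: perspective taking -> policy inference -> action prediction
#' -> next-state prediction -> safety evaluation. If any pedestrian is
#' judged unsafe, the bystander helps the first such pedestrian: the
#' pedestrian's action is overridden to `"stay"` for this step, the
#' bystander itself stays, and it incurs the help cost. Otherwise the
#' bystander pursues its own goal through its decision network. At most one
#' pedestrian is helped per step.
#'
#' @param nets a trained [tom_networks()] bundle.
#' @param policy_net the bystander's own [decision_network()].
#' @param world the current `gridworld`.
#' @param state the running [tom_state_init()] state.
#' @return a list with `action` (the bystander's action), `help` (logical),
#'   `helped_id` (id of the stopped pedestrian or `NA`), `estimates` (one
#'   `tom_estimate` per evaluated pedestrian: inferred observation, style,
#'   predicted action, predicted next cell, safety), and the updated
#'   `state`.
#' @export
bystander_step <- function(nets, policy_net, world, state) {
  bid <- state$bystander_id
  self_obs <- observe(world, bid)
  own_action <- .act_full(policy_net, self_obs, epsilon = 0)$action
  own_next <- .move_result(world, self_obs$self_position, own_action)$cell
  ped_ids <- sort(as.integer(names(state$per)))
  # First pass: run perspective taking, policy inference and action
  # prediction for every visible pedestrian.
  pred <- list()
  for (k in ped_ids) {
    ag <- world$agents[[k]]
    if (ag$done) next
    st <- state$per[[as.character(k)]]
    obs_hat <- infer_other_observation(nets$perspective, self_obs, k, world)
    if (is.null(obs_hat)) next # occluded: keep cached estimates
    cur_pos <- self_obs$visible_agents[[as.character(k)]]
    bits <- policy_bits(st$prev_pos, cur_pos, world$agents[[k]]$goal,
                        world$walls,
                        occupied = state$prev_occupied %||% list(),
                        last_safety = st$safety)
    style <- infer_behavior_style(nets$policy, st$style, bits)
    a_hat <- predict_other_action(nets$action, obs_hat, style)
    mv <- .move_result(world, cur_pos, a_hat)
    pred[[as.character(k)]] <- list(obs_hat = obs_hat, style = style,
                                    a_hat = a_hat, cur_pos = cur_pos,
                                    cell = mv$cell, blocked = mv$blocked)
  }
  # Second pass: evaluate each pedestrian's safety on the jointly
  # hypothesised next configuration -- every other agent placed at its
  # predicted next cell (the bystander at its own planned cell) -- which is
  # the same geometry the network was trained on.
  estimates <- list()
  helped_id <- NA_integer_
  for (key in names(pred)) {
    k <- as.integer(key)
    p <- pred[[key]]
    others <- list()
    others_now <- list()
    others[[as.character(bid)]] <- own_next
    others_now[[as.character(bid)]] <- self_obs$self_position
    for (key2 in names(pred)) {
      if (key2 != key) {
        others[[key2]] <- pred[[key2]]$cell
        others_now[[key2]] <- pred[[key2]]$cur_pos
      }
    }
    for (ag in world$agents) { # agents visible but not chained stay put
      if (ag$done || ag$id == bid || ag$id == k) next
      if (is.null(others[[as.character(ag$id)]])) {
        others[[as.character(ag$id)]] <- ag$position
        others_now[[as.character(ag$id)]] <- ag$position
      }
    }
    ps <- predicted_state(world$walls, p$cell, others = others,
                          blocked = p$blocked, others_now = others_now,
                          origin = p$cur_pos)
    safety <- evaluate_safety(nets$safety, ps)
    estimates[[key]] <- structure(
      list(other_id = k, other_observation = p$obs_hat, style = p$style,
           predicted_action = p$a_hat, predicted_state = p$cell,
           safety = safety),
      class = "tom_estimate"
    )
    st <- state$per[[key]]
    st$prev_pos <- p$cur_pos
    st$style <- p$style
    st$safety <- safety
    state$per[[key]] <- st
    if (is.na(helped_id) && safety == "unsafe") helped_id <- k
  }
  state$prev_occupied <- .active_positions(world)
  help <- !is.na(helped_id)
  action <- if (help) "stay" else own_action
  list(action = action, help = help, helped_id = helped_id,
       estimates = estimates, state = state)
}

#' Train the ToM networks by observing pedestrians
#'
#' Runs `cfg$episodes` observation episodes. Odd episodes contain one
#' pedestrian and a wall segment (occlusion and wall-bump examples); even
#' episodes contain two pedestrians and no walls (agent-agent collision
#' examples). Pedestrian styles are drawn uniformly per episode and each
#' pedestrian acts greedily through its trained decision network (or the
#' scripted policies). The observing bystander pursues its own goal while
#' watching, so the observed interaction density matches what it will face
#' during evaluation, and, per step and per visible pedestrian:
#' \itemize{
#'   \item updates the policy-inference network with R-STDP using the style
#'     reward \eqn{e_{bs}} against the pedestrian's true style;
#'   \item updates the action-prediction network with R-STDP using
#'     \eqn{e_{action} = +1/-1} against the pedestrian's executed action;
#'   \item updates the state-evaluation network with the same
#'     reward-modulated rule, using the observed collision outcome of the
#'     executed action as the teacher signal (+1 when the safe/unsafe
#'     decision matches the outcome, -1 otherwise).
#' }
#' All three learn with a mistake-driven, teacher-corrected rule: nothing
#' changes while the expressed judgment matches the outcome by a
#' comfortable activity margin; otherwise the wrongly expressed population
#' is depressed and the true one receives a corrective stimulation trace.
#' The rule self-limits, so no learning-rate schedule is needed. The
#' perspective network is fixed and never updated.
#'
#' @param cfg a [training_config()] (300 episodes by default).
#' @param policy_nets named list of trained decision networks, one per
#'   style, used to drive the pedestrians.
#' @param nets optional starting [tom_networks()]; a fresh bundle seeded
#'   from `child_seed(cfg$rng_seed, 2)` by default.
#' @param window network window length (when `nets` is NULL).
#' @param use_scripted drive pedestrians with [scripted_policy()] instead of
#'   the trained networks.
#' @return the trained `tom_networks`; per-episode prediction accuracies are
#'   attached as `attr(nets, "log")`.
#' @export
train_tom <- function(cfg = training_config(), policy_nets = NULL,
                      nets = NULL, window = 50L, use_scripted = FALSE) {
  if (is.null(nets)) {
    nets <- tom_networks(seed = child_seed(cfg$rng_seed, 2L), window = window)
  }
  if (!use_scripted && is.null(policy_nets)) {
    .stopf("policy_nets required unless use_scripted = TRUE")
  }
  log <- data.frame(episode = integer(), style_acc = numeric(),
                    action_acc = numeric(), safety_acc = numeric(),
                    unsafe_recall = numeric())
  for (ep in seq_len(cfg$episodes)) {
    set.seed(child_seed(cfg$rng_seed, 200L + ep))
    n_ped <- if (ep %% 2L == 1L) 1L else 2L
    styles <- sample(STYLES, n_ped, replace = TRUE)
    world <- generate_environment(NULL, n_agents = 1L + n_ped,
                                  with_walls = (n_ped == 1L),
                                  policies = c("reckless", styles))
    state <- tom_state_init(world, 1L)
    hits <- c(style = 0, action = 0, safety = 0, n = 0,
              unsafe_hit = 0, unsafe_n = 0, e_bs = 0)
    steps <- 0L
    while (steps < cfg$step_cap &&
           any(!vapply(world$agents[-1], `[[`, TRUE, "done"))) {
      if (world$agents[[1]]$done) break # the observer has left the grid
      self_obs <- observe(world, 1L)
      pending <- list()
      for (k in 1L + seq_len(n_ped)) {
        ag <- world$agents[[k]]
        if (ag$done) next
        obs_hat <- infer_other_observation(nets$perspective, self_obs, k, world)
        if (is.null(obs_hat)) next
        st <- state$per[[as.character(k)]]
        cur_pos <- ag$position
        bits <- policy_bits(st$prev_pos, cur_pos, ag$goal, world$walls,
                            occupied = state$prev_occupied %||% list(),
                            last_safety = st$safety)
        sf <- .infer_style_full(nets$policy, st$style, bits)
        # training expression is epsilon-greedy over styles: an undecided
        # or sticky readout would otherwise rarely express the true class,
        # and the +-1 grading could never credit it
        expressed <- if (runif(1) < 0.3 || is.na(sf$raw)) {
          STYLES[sample.int(3L, 1L)]
        } else {
          sf$raw
        }
        e_bs <- style_reward(expressed, ag$policy)
        hits["e_bs"] <- hits["e_bs"] + e_bs
        nets$policy$syn <- .perceptron_rstdp(nets$policy, sf$post,
                                             expressed, ag$policy, sf$active)
        # the recurrence is structural: re-pin it after the plastic update
        nets$policy$syn$weights[, 1:6] <- .style_persistence_weights()
        sf$style <- expressed
        hits["style"] <- hits["style"] +
          as.numeric(!is.na(sf$raw) && sf$raw == ag$policy)
        act_active <- .action_pred_active(obs_hat, sf$style)
        act_post <- .net_forward(nets$action, act_active)
        a_hat <- .net_decode(nets$action, act_post)
        a_hat_use <- if (is.na(a_hat)) ACTIONS[sample.int(5L, 1L)] else a_hat
        pending[[as.character(k)]] <- list(
          style = sf$style, act_active = act_active, act_post = act_post,
          a_hat = a_hat_use, cur_pos = cur_pos
        )
        st$prev_pos <- cur_pos
        st$style <- sf$style
        state$per[[as.character(k)]] <- st
      }
      state$prev_occupied <- .active_positions(world)
      actions <- list()
      # the observer pursues its own goal while watching (self-experience
      # in the same interaction density it will face as a bystander)
      if (!world$agents[[1]]$done) {
        obs_1 <- observe(world, 1L)
        actions[["1"]] <- if (use_scripted) {
          scripted_policy("reckless", obs_1)
        } else {
          act(policy_nets[["reckless"]], obs_1)
        }
      }
      for (k in 1L + seq_len(n_ped)) {
        ag <- world$agents[[k]]
        if (ag$done) next
        obs_k <- observe(world, k)
        actions[[as.character(k)]] <- if (use_scripted) {
          scripted_policy(ag$policy, obs_k)
        } else {
          act(policy_nets[[ag$policy]], obs_k)
        }
      }
      res <- step_world(world, actions)
      for (key in names(pending)) {
        p <- pending[[key]]
        k <- as.integer(key)
        a_actual <- actions[[key]]
        e_action <- if (p$a_hat == a_actual) 1 else -1
        nets$action$syn <- .perceptron_rstdp(nets$action, p$act_post,
                                             p$a_hat, a_actual, p$act_active)
        hits["action"] <- hits["action"] + as.numeric(e_action > 0)
        # State evaluation: the observer mentally simulates every candidate
        # move of the observed agent and grades each hypothesised state by
        # the collision predicate (risk neurons fire on collision states);
        # the sweep over alternatives supplies the rare collision
        # geometries that executed behaviour alone undersamples.
        others_next <- .active_positions(res$world, exclude = k)
        others_pre <- .active_positions(world, exclude = k)
        v_use <- "safe"
        for (a_cand in ACTIONS) {
          mv <- .move_result(world, p$cur_pos, a_cand)
          ps <- predicted_state(world$walls, mv$cell, others = others_next,
                                blocked = mv$blocked,
                                others_now = others_pre,
                                origin = p$cur_pos)
          collided <- .collision_predicate(ps)
          saf_active <- which(encode_relative_state(ps$walls, ps$focus,
                                                    ps$others, ps$blocked,
                                                    ps$others_now,
                                                    ps$origin) == 1L)
          saf_post <- .net_forward(nets$safety, saf_active)
          v_hat <- .net_decode(nets$safety, saf_post)
          v_this <- if (is.na(v_hat)) {
            SAFETY_LABELS[sample.int(2L, 1L)]
          } else {
            v_hat
          }
          truth_label <- if (collided) "unsafe" else "safe"
          nets$safety$syn <- .perceptron_rstdp(nets$safety, saf_post,
                                               v_this, truth_label,
                                               saf_active)
          if (a_cand == a_actual) {
            correct <- (v_this == "unsafe") == collided
            hits["safety"] <- hits["safety"] + as.numeric(correct)
            if (collided) {
              hits["unsafe_n"] <- hits["unsafe_n"] + 1
              hits["unsafe_hit"] <- hits["unsafe_hit"] +
                as.numeric(v_this == "unsafe")
            }
            v_use <- v_this
          }
        }
        st <- state$per[[key]]
        st$safety <- v_use
        state$per[[key]] <- st
        hits["n"] <- hits["n"] + 1
      }
      world <- res$world
      steps <- steps + 1L
    }
    if (hits["n"] > 0) {
      log <- rbind(log, data.frame(
        episode = ep, style_acc = hits["style"] / hits["n"],
        action_acc = hits["action"] / hits["n"],
        safety_acc = hits["safety"] / hits["n"],
        unsafe_recall = if (hits["unsafe_n"] > 0) {
          hits["unsafe_hit"] / hits["unsafe_n"]
        } else NA_real_,
        row.names = NULL
      ))
    }
  }
  attr(nets, "log") <- log
  nets
}
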