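test_that("perspective taking reproduces the other agent's observation
           when nothing is occluded, and suppresses what the other cannot
           see", {
  pn <- perspective_network()
  w <- generate_environment(seed = 41, with_walls = FALSE)
  self_obs <- observe(w, 1)
  hat <- infer_other_observation(pn, self_obs, 2L, w)
  direct <- observe(w, 2)
  expect_equal(hat$self_position, direct$self_position)
  expect_equal(hat$goal, direct$goal)
  expect_equal(hat$visibility, direct$visibility)
  expect_setequal(names(hat$visible_agents), names(direct$visible_agents))

  # constructed occlusion: self sees agent 3, but 3 is hidden from 2's
  # viewpoint, so 3 must be absent from the inferred observation
  w2 <- fixture_layout_world(walls = rbind(c(4, 3), c(4, 4), c(4, 5)),
                             starts = list(c(4, 1), c(2, 4), c(6, 4)),
                             goals = list(c(7, 7), c(1, 1), c(7, 1)))
  so <- observe(w2, 1)
  expect_false(is.null(so$visible_agents[["3"]])) # self sees it
  expect_false(visible_cells(w2, c(2, 4))[6, 4])  # 2 cannot
  hat2 <- infer_other_observation(perspective_network(), so, 2L, w2)
  expect_null(hat2$visible_agents[["3"]])

  # an invisible target yields NULL (callers keep their cached estimate)
  so3 <- observe(w2, 2)
  expect_null(infer_other_observation(perspective_network(), so3, 3L, w2))
})

test_that("the inferred observation equals direct observation whenever the
           observer's knowledge covers the other's visible region", {
  set.seed(42)
  checked <- 0
  for (i in 1:200) {
    w <- generate_environment(NULL)
    self_obs <- observe(w, 1)
    for (k in 2:3) {
      if (is.null(self_obs$visible_agents[[as.character(k)]])) next
      direct <- observe(w, k)
      covered <- all(vapply(names(direct$visible_agents), function(id) {
        id == "1" || !is.null(self_obs$visible_agents[[id]])
      }, TRUE))
      if (!covered) next
      hat <- infer_other_observation(perspective_network(), self_obs, k, w)
      expect_setequal(names(hat$visible_agents),
                      names(direct$visible_agents))
      for (id in names(direct$visible_agents)) {
        expect_equal(hat$visible_agents[[id]], direct$visible_agents[[id]])
      }
      checked <- checked + 1
    }
  }
  expect_gt(checked, 100)
})

test_that("style prediction rewards are +1/-1 and bounded", {
  expect_equal(style_reward("cautious", "cautious"), 1)
  expect_equal(style_reward("reckless", "cautious"), -1)
  expect_equal(style_reward(NA, "cautious"), -1)
  for (a in c("reckless", "experienced", "cautious")) {
    for (b in c("reckless", "experienced", "cautious")) {
      e <- style_reward(a, b)
      expect_true(e >= -1 && e <= 1)
      expect_true(e %in% c(-1, 1))
    }
  }
  # the gamma/beta form: e = -gamma * mismatch + beta
  expect_equal(style_reward("a", "b", gamma = 3, beta = 0.5), -2.5)
})

test_that("single-agent movement prediction equals step_world restricted
           to one agent, over all cells and actions", {
  w <- fixture_world()
  wall_keys <- paste(w$walls[, 1], w$walls[, 2])
  for (r in 1:7) {
    for (c in 1:7) {
      if (paste(r, c) %in% wall_keys) next
      for (a in c("up", "down", "left", "right", "stay")) {
        got <- predict_next_state(w, c(r, c), a)
        # oracle: a single-agent world stepped with this action
        solo <- w
        solo$agents <- list(agent_state(1, c(r, c), "reckless", c(7, 7)))
        if (all(c(r, c) == c(7, 7))) solo$agents[[1]]$goal <- c(1, 1)
        res <- step_world(solo, list("1" = a))
        expect_equal(got, res$world$agents[[1]]$position,
                     label = sprintf("cell (%d,%d) action %s", r, c, a))
      }
    }
  }
  expect_equal(predict_next_state(w, c(3, 3), "stay"), c(3, 3))
  expect_error(predict_next_state(w, c(0, 3), "up"), "off-grid")
})

test_that("behaviour bits summarise the observed move", {
  walls <- rbind(c(4, 4))
  b <- policy_bits(c(3, 2), c(3, 3), goal = c(3, 7), walls = walls)
  expect_equal(b[1], 1L) # moved toward goal
  expect_equal(b[2], 0L)
  b2 <- policy_bits(c(3, 3), c(3, 3), goal = c(3, 7), walls = walls,
                    last_safety = "safe")
  expect_equal(b2[6], 1L) # stayed
  expect_equal(b2[8], 1L) # last judged safe
  b3 <- policy_bits(c(3, 4), c(2, 4), goal = c(3, 7), walls = walls)
  expect_equal(b3[3], 1L) # moved away from the wall
  expect_equal(b3[4], 0L) # and is no longer within one cell of it
  # avoided an occupied goal-ward cell
  b4 <- policy_bits(c(3, 4), c(2, 4), goal = c(3, 6), walls = NULL,
                    occupied = list(c(3, 5)))
  expect_equal(b4[5], 1L)
})

test_that("an untrained style network keeps the previous estimate and the
           trained one recognises a scripted cautious agent within five
           steps", {
  fresh <- tom_networks(seed = 5, window = 20)
  expect_equal(infer_behavior_style(fresh$policy, "experienced",
                                    rep(0L, 8)), "experienced")

  nets <- fixture_tom()
  set.seed(43)
  votes <- c(cautious = 0, other = 0)
  for (rep in 1:10) {
    w <- generate_environment(NULL, n_agents = 2, with_walls = TRUE,
                              policies = c("reckless", "cautious"))
    est <- NA_character_
    prev <- NULL
    seen <- character(0)
    for (s in 1:5) {
      if (w$agents[[2]]$done) break
      a2 <- scripted_policy("cautious", observe(w, 2))
      cur <- w$agents[[2]]$position
      bits <- policy_bits(prev, cur, w$agents[[2]]$goal, w$walls)
      est <- infer_behavior_style(nets$policy, est, bits)
      if (!is.na(est)) seen <- c(seen, est)
      prev <- cur
      w <- step_world(w, list("1" = "stay", "2" = a2))$world
    }
    if (length(seen)) {
      maj <- names(sort(table(seen), decreasing = TRUE))[1]
      votes[ifelse(maj == "cautious", "cautious", "other")] <-
        votes[ifelse(maj == "cautious", "cautious", "other")] + 1
    }
  }
  expect_gt(votes[["cautious"]], votes[["other"]])
})

test_that("held-out style classification of scripted agents beats
           chance", {
  nets <- fixture_tom()
  set.seed(44)
  hits <- 0; total <- 0
  for (rep in 1:45) {
    style <- c("reckless", "experienced", "cautious")[(rep %% 3) + 1]
    w <- generate_environment(NULL, n_agents = 2, with_walls = TRUE,
                              policies = c("reckless", style))
    est <- NA_character_
    prev <- NULL
    seen <- character(0)
    for (s in 1:8) {
      if (w$agents[[2]]$done) break
      a2 <- scripted_policy(style, observe(w, 2))
      cur <- w$agents[[2]]$position
      bits <- policy_bits(prev, cur, w$agents[[2]]$goal, w$walls)
      est <- infer_behavior_style(nets$policy, est, bits)
      if (!is.na(est)) seen <- c(seen, est)
      prev <- cur
      w <- step_world(w, list("1" = "stay", "2" = a2))$world
    }
    if (length(seen)) {
      maj <- names(sort(table(seen), decreasing = TRUE))[1]
      hits <- hits + (maj == style)
      total <- total + 1
    }
  }
  expect_gt(hits / total, 1 / 3)
})

test_that("action prediction on a deterministic scripted reckless agent
           beats chance on held-out states", {
  nets <- fixture_tom()
  set.seed(45)
  hits <- 0; total <- 0
  for (i in 1:40) {
    w <- generate_environment(NULL, n_agents = 2, with_walls = TRUE,
                              policies = c("reckless", "reckless"))
    self_obs <- observe(w, 1)
    hat <- infer_other_observation(nets$perspective, self_obs, 2L, w)
    if (is.null(hat)) next
    a_hat <- predict_other_action(nets$action, hat, "reckless")
    a_true <- scripted_policy("reckless", observe(w, 2))
    hits <- hits + (a_hat == a_true)
    total <- total + 1
  }
  expect_gt(hits / total, 1 / 5)
})

test_that("an unknown style falls back to a uniform prior over the style
           blocks and a silent action readout predicts staying", {
  w <- generate_environment(seed = 46, with_walls = FALSE)
  hat <- infer_other_observation(perspective_network(), observe(w, 1), 2L, w)
  active_na <- tomsnn:::.action_pred_active(hat, NA)
  active_one <- tomsnn:::.action_pred_active(hat, "reckless")
  expect_equal(length(active_na), 3 * length(active_one))
  zero <- tom_networks(seed = 6, window = 20)
  zero$action$syn$weights[] <- 0
  zero$action$bias <- 0
  expect_equal(predict_other_action(zero$action, hat, "reckless"), "stay")
})

test_that("after training, safety evaluation matches the collision
           predicate on an enumerated state set", {
  nets <- fixture_tom()
  walls <- rbind(c(4, 4))
  states <- list()
  # enumerated grid of two-agent configurations around the centre
  for (dr in -2:2) {
    for (dc in -2:2) {
      other <- c(4 + dr, 5 + dc)
      if (any(other < 1) || any(other > 7)) next
      if (all(other == c(4, 4))) next
      states[[length(states) + 1]] <-
        predicted_state(walls, c(4, 5), others = list("2" = other),
                        blocked = FALSE)
    }
  }
  # plus blocked-move states at assorted cells
  for (cell in list(c(3, 4), c(5, 4), c(1, 1), c(6, 2))) {
    states[[length(states) + 1]] <-
      predicted_state(walls, cell, others = list(), blocked = TRUE)
  }
  agree <- vapply(states, function(ps) {
    truth <- if (tomsnn:::.collision_predicate(ps)) "unsafe" else "safe"
    evaluate_safety(nets$safety, ps) == truth
  }, TRUE)
  expect_gte(mean(agree), 0.9)

  # an isolated agent with nothing nearby is safe
  expect_equal(evaluate_safety(nets$safety,
                               predicted_state(walls, c(7, 7))), "safe")
  # two agents on one cell are unsafe
  expect_equal(evaluate_safety(nets$safety,
                               predicted_state(NULL, c(4, 4),
                                               others = list("2" = c(4, 4)))),
               "unsafe")
})

test_that("ToM training is reproducible, keeps weights bounded, and never
           touches the perspective stage", {
  cfg <- training_config(episodes = 12L, rng_seed = 3L)
  n1 <- train_tom(cfg, use_scripted = TRUE, window = 15)
  n2 <- train_tom(cfg, use_scripted = TRUE, window = 15)
  expect_identical(n1$policy$syn$weights, n2$policy$syn$weights)
  expect_identical(n1$action$syn$weights, n2$action$syn$weights)
  expect_identical(n1$safety$syn$weights, n2$safety$syn$weights)
  for (net in list(n1$policy, n1$action, n1$safety)) {
    expect_true(all(net$syn$weights >= -1 & net$syn$weights <= 1))
  }
  expect_identical(unclass(n1$perspective), unclass(perspective_network()))
})

test_that("the bystander helps exactly when some pedestrian is judged
           unsafe, stopping that pedestrian", {
  nets <- fixture_tom()
  net_b <- decision_network(seed = 8, window = 20)
  set.seed(47)
  saw_help <- FALSE
  saw_no_help <- FALSE
  for (i in 1:40) {
    w <- generate_environment(NULL, n_agents = 3, with_walls = TRUE)
    state <- tom_state_init(w, 1L)
    for (s in 1:6) {
      bs <- bystander_step(nets, net_b, w, state)
      state <- bs$state
      unsafe_ids <- vapply(bs$estimates, function(e) e$safety == "unsafe",
                           TRUE)
      expect_equal(bs$help, any(unsafe_ids))
      if (bs$help) {
        expect_true(bs$helped_id %in% as.integer(names(which(unsafe_ids))))
        expect_equal(bs$action, "stay")
        saw_help <- TRUE
      } else {
        saw_no_help <- TRUE
      }
      # estimate consistency: predicted state is the movement rule applied
      # to the pedestrian's position and predicted action
      for (e in bs$estimates) {
        expect_equal(e$predicted_state,
                     predict_next_state(w, w$agents[[e$other_id]]$position,
                                        e$predicted_action))
      }
      acts <- list()
      for (k in 1:3) {
        if (w$agents[[k]]$done) next
        acts[[as.character(k)]] <- if (k == 1) bs$action else
          if (!is.na(bs$helped_id) && bs$helped_id == k) "stay" else
            scripted_policy(w$agents[[k]]$policy, observe(w, k))
      }
      w <- step_world(w, acts)$world
      if (all(vapply(w$agents, `[[`, TRUE, "done"))) break
    }
    if (saw_help && saw_no_help) break
  }
  expect_true(saw_help)
  expect_true(saw_no_help)
})
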