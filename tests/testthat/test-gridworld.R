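test_that("environment generation is seed-deterministic and always
           yields reachable goals off the walls", {
  w1 <- generate_environment(seed = 77)
  w2 <- generate_environment(seed = 77)
  expect_identical(w1[c("size", "walls")], w2[c("size", "walls")])
  expect_identical(lapply(w1$agents, unclass), lapply(w2$agents, unclass))

  for (i in 1:400) {
    w <- generate_environment(seed = 100000 + i)
    wall_keys <- paste(w$walls[, 1], w$walls[, 2])
    goals <- vapply(w$agents, function(a) paste(a$goal, collapse = " "), "")
    expect_equal(anyDuplicated(goals), 0)
    starts <- vapply(w$agents, function(a) paste(a$position, collapse = " "), "")
    expect_equal(anyDuplicated(starts), 0)
    for (a in w$agents) {
      expect_false(paste(a$position[1], a$position[2]) %in% wall_keys)
      expect_false(paste(a$goal[1], a$goal[2]) %in% wall_keys)
      d <- bfs_distances(w$walls, a$goal) # BFS reachability oracle
      expect_true(is.finite(d[a$position[1], a$position[2]]))
    }
    expect_length(w$agents, 3)
  }
})

test_that("visibility equals the brute-force line-of-sight oracle on all
           cells and is symmetric", {
  set.seed(13)
  for (i in 1:12) {
    w <- generate_environment(NULL)
    vps <- list(c(1, 1), c(4, 4), w$agents[[1]]$position)
    for (vp in vps) {
      mask <- visible_cells(w, vp)
      expect_true(mask[vp[1], vp[2]])
      for (r in 1:7) {
        for (c in 1:7) {
          expect_equal(mask[r, c], oracle_visible(w$walls, vp, c(r, c)),
                       label = sprintf("world %d vp (%d,%d) cell (%d,%d)",
                                       i, vp[1], vp[2], r, c))
        }
      }
    }
    # symmetry of the centre-to-centre rule
    for (j in 1:20) {
      a <- c(sample(7, 1), sample(7, 1))
      b <- c(sample(7, 1), sample(7, 1))
      expect_equal(visible_cells(w, a)[b[1], b[2]],
                   visible_cells(w, b)[a[1], a[2]])
    }
  }
  expect_error(visible_cells(generate_environment(seed = 1), c(0, 3)),
               "off-grid")
})

test_that("a world with no walls is fully observable", {
  w <- generate_environment(seed = 21, with_walls = FALSE)
  expect_true(all(visible_cells(w, c(3, 5))))
  obs <- observe(w, 1)
  expect_length(obs$visible_agents, 2) # all other agents listed
})

test_that("observation hides exactly the occluded agents", {
  # wall between agent 1 (above) and agent 2 (below); agent 3 off to the side
  w <- fixture_layout_world()
  expect_false(visible_cells(w, c(2, 4))[6, 4])
  obs <- observe(w, 1)
  expect_null(obs$visible_agents[["2"]]) # behind the wall
  expect_false(is.null(obs$visible_agents[["3"]]))
  expect_error(observe(w, 9), "unknown agent")
})

test_that("simultaneous movement, blocking and collision flags follow the
           world rules", {
  w <- fixture_layout_world(walls = rbind(c(4, 4)),
                            starts = list(c(3, 4), c(5, 4), c(1, 1)),
                            goals = list(c(1, 7), c(7, 7), c(7, 1)))
  # all stay: nothing moves, nothing collides
  res <- step_world(w, list("1" = "stay", "2" = "stay", "3" = "stay"))
  expect_equal(res$world$agents[[1]]$position, c(3L, 4L))
  expect_false(any(vapply(res$transitions[1:3], `[[`, TRUE, "collided")))

  # moving into a wall (or off-grid) blocks and flags a collision, but not
  # an agent-agent collision
  res <- step_world(w, list("1" = "down", "2" = "up", "3" = "up"))
  expect_equal(res$world$agents[[1]]$position, c(3L, 4L))
  expect_true(res$transitions[["1"]]$collided)
  expect_false(res$transitions[["1"]]$collided_agent)
  expect_true(res$transitions[["3"]]$collided) # off-grid bump
  expect_equal(res$world$agents[[3]]$position, c(1L, 1L))

  # two agents entering one cell are both flagged and pass through
  w2 <- fixture_layout_world(walls = NULL,
                             starts = list(c(4, 2), c(4, 4), c(1, 1)),
                             goals = list(c(7, 7), c(1, 7), c(7, 1)))
  w2$walls <- NULL
  res <- step_world(w2, list("1" = "right", "2" = "left", "3" = "stay"))
  expect_true(res$transitions[["1"]]$collided_agent)
  expect_true(res$transitions[["2"]]$collided_agent)
  expect_false(res$transitions[["3"]]$collided)
  expect_equal(res$world$agents[[1]]$position, c(4L, 3L))
  expect_equal(res$world$agents[[2]]$position, c(4L, 3L))

  # agent count is conserved and done agents never move
  w3 <- fixture_layout_world(walls = NULL,
                             starts = list(c(1, 2), c(7, 7), c(5, 5)),
                             goals = list(c(1, 1), c(6, 7), c(2, 2)))
  w3$walls <- NULL
  res <- step_world(w3, list("1" = "left", "2" = "up", "3" = "up"))
  expect_length(res$world$agents, 3)
  expect_true(res$world$agents[[1]]$done)
  expect_equal(res$world$agents[[1]]$steps, 1L)
  res2 <- step_world(res$world, list("2" = "stay", "3" = "up"))
  expect_equal(res2$world$agents[[1]]$position, c(1L, 1L))
  expect_null(res2$transitions[["1"]])
  expect_error(step_world(w3, list("1" = "left")), "missing or invalid")
})

test_that("style rewards follow their definitions", {
  tr <- function(dp0, dp1, dw0 = Inf, dw1 = Inf, coll = FALSE) {
    structure(list(dp_prev = dp0, dp_now = dp1, dw_prev = dw0, dw_now = dw1,
                   collided = coll, collided_agent = coll),
              class = "transition")
  }
  expect_equal(compute_reward("reckless", tr(2, 1)), 0.5)
  expect_equal(compute_reward("reckless", tr(3, 3)), 0) # stay
  expect_equal(compute_reward("reckless", tr(1, 2)), -1)
  expect_equal(compute_reward("reckless", tr(2, 1, coll = TRUE)), 0.5)

  expect_equal(compute_reward("experienced", tr(2, 1)), 0.5)
  expect_equal(compute_reward("experienced", tr(2, 1, coll = TRUE)), -5)

  # cautious: the wall term engages within one cell of a wall
  expect_equal(compute_reward("cautious", tr(2, 1, dw0 = 1, dw1 = 2)),
               0.5 + 1)
  expect_equal(compute_reward("cautious", tr(2, 1, dw0 = 2, dw1 = 1)), 0.5)
  expect_equal(compute_reward("cautious", tr(2, 1, dw0 = 1, dw1 = 1,
                                             coll = TRUE)), -5)
  expect_error(compute_reward("reckless", tr(0, 1)), "dp_prev")
  expect_error(compute_reward("bold", tr(2, 1)), "unknown policy")

  # reckless reward is at most 1 and positive iff strictly closer
  set.seed(14)
  for (i in 1:50) {
    d0 <- runif(1, 0.5, 9)
    d1 <- runif(1, 0, 9)
    r <- compute_reward("reckless", tr(d0, d1))
    expect_lte(r, 1)
    expect_equal(r > 0, d1 < d0)
  }
})

test_that("world layouts survive a JSON round trip", {
  w <- fixture_world()
  path <- tempfile(fileext = ".json")
  save_world(w, path)
  w2 <- load_world(path)
  expect_equal(w2$walls, w$walls, ignore_attr = TRUE)
  expect_equal(lapply(w2$agents, `[[`, "position"),
               lapply(w$agents, `[[`, "position"))
  expect_equal(lapply(w2$agents, `[[`, "goal"),
               lapply(w$agents, `[[`, "goal"))
  expect_identical(w2$vis, w$vis)
  unlink(path)
})
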