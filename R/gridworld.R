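#' @rdname generate_environment
#' @export
agent_state <- function(id, position, policy = "reckless", goal,
                        done = FALSE) {
  structure(list(id = as.integer(id), position = as.integer(position),
                 policy = policy, goal = as.integer(goal), done = done,
                 steps = NA_integer_, ever_collided = FALSE),
            class = "agent_state")
}

.euclid <- function(a, b) sqrt(sum((a - b)^2))

# Euclidean distance (in cells, centre to centre) from `cell` to the nearest
# wall cell; Inf when the world has no walls.
.wall_distance <- function(walls, cell) {
  if (is.null(walls) || nrow(walls) == 0L) return(Inf)
  sqrt(min((walls[, 1] - cell[1])^2 + (walls[, 2] - cell[2])^2))
}

# Breadth-first shortest-path distances from `target` over the grid with
# walls blocked; Inf where unreachable. Returns a size x size matrix.
bfs_distances <- function(walls, target, size = GRID_SIZE) {
  dist <- matrix(Inf, size, size)
  blocked <- matrix(FALSE, size, size)
  if (!is.null(walls) && nrow(walls)) blocked[walls] <- TRUE
  if (blocked[target[1], target[2]]) return(dist)
  dist[target[1], target[2]] <- 0
  queue <- matrix(target, ncol = 2)
  while (nrow(queue)) {
    nxt <- NULL
    for (i in seq_len(nrow(queue))) {
      r <- queue[i, 1]; c <- queue[i, 2]
      d <- dist[r, c]
      for (k in 1:4) {
        nr <- r + ACTION_DELTAS[k, 1]; nc <- c + ACTION_DELTAS[k, 2]
        if (nr >= 1 && nr <= size && nc >= 1 && nc <= size &&
            !blocked[nr, nc] && dist[nr, nc] > d + 1) {
          dist[nr, nc] <- d + 1
          nxt <- rbind(nxt, c(nr, nc))
        }
      }
    }
    queue <- if (is.null(nxt)) matrix(numeric(0), ncol = 2) else nxt
  }
  dist
}

# Does the open segment between the centres of cells `from` and `to`
# intersect the square of any wall cell (excluding the endpoint cells) with
# positive length? Cell (r, c) occupies the square [r-1, r] x [c-1, c]; its
# centre is (r - 0.5, c - 0.5). A corner touch (zero-length intersection)
# does not block, which keeps the rule symmetric in its endpoints.
.segment_blocked <- function(walls, from, to) {
  if (is.null(walls) || nrow(walls) == 0L) return(FALSE)
  p <- c(from[1] - 0.5, from[2] - 0.5)
  d <- c(to[1] - 0.5, to[2] - 0.5) - p
  for (i in seq_len(nrow(walls))) {
    w <- walls[i, ]
    if (all(w == from) || all(w == to)) next
    t0 <- 0; t1 <- 1
    ok <- TRUE
    for (ax in 1:2) {
      lo <- w[ax] - 1; hi <- w[ax]
      if (d[ax] == 0) {
        if (p[ax] < lo || p[ax] > hi) { ok <- FALSE; break }
      } else {
        ta <- (lo - p[ax]) / d[ax]
        tb <- (hi - p[ax]) / d[ax]
        if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
        t0 <- max(t0, ta); t1 <- min(t1, tb)
        if (t0 >= t1) { ok <- FALSE; break }
      }
    }
    if (ok && t1 - t0 > 1e-9) return(TRUE)
  }
  FALSE
}

# Full visibility mask from one viewpoint: a cell is visible iff the
# straight segment between cell centres crosses no wall cell interior.
.visibility_from <- function(walls, viewpoint, size = GRID_SIZE) {
  vis <- matrix(TRUE, size, size)
  if (is.null(walls) || nrow(walls) == 0L) return(vis)
  for (r in seq_len(size)) {
    for (c in seq_len(size)) {
      if (r == viewpoint[1] && c == viewpoint[2]) next
      vis[r, c] <- !.segment_blocked(walls, viewpoint, c(r, c))
    }
  }
  vis
}

# All-pairs cell-to-cell visibility (row-major cell indices), vectorised
# over every (from, to) pair per wall cell via Liang-Barsky clipping.
.vis_all_pairs <- function(walls, size = GRID_SIZE) {
  n <- size * size
  if (is.null(walls) || nrow(walls) == 0L) return(matrix(TRUE, n, n))
  # row-major index k = (r - 1) * size + c; centres at (r - 0.5, c - 0.5)
  rr <- rep(seq_len(size), each = size) - 0.5
  cc <- rep(seq_len(size), times = size) - 0.5
  from_r <- rep(rr, times = n); from_c <- rep(cc, times = n)
  to_r <- rep(rr, each = n); to_c <- rep(cc, each = n)
  d_r <- to_r - from_r; d_c <- to_c - from_c
  blocked <- rep(FALSE, n * n)
  clip_axis <- function(p, d, lo, hi, t0, t1, alive) {
    par <- d == 0
    alive <- alive & !(par & (p < lo | p > hi))
    ta <- (lo - p) / d
    tb <- (hi - p) / d
    swap <- ta > tb
    tmp <- ta[swap]; ta[swap] <- tb[swap]; tb[swap] <- tmp
    upd <- alive & !par
    t0[upd] <- pmax(t0[upd], ta[upd])
    t1[upd] <- pmin(t1[upd], tb[upd])
    list(t0 = t0, t1 = t1, alive = alive)
  }
  for (i in seq_len(nrow(walls))) {
    w <- walls[i, ]
    t0 <- rep(0, n * n); t1 <- rep(1, n * n); alive <- rep(TRUE, n * n)
    res <- clip_axis(from_r, d_r, w[1] - 1, w[1], t0, t1, alive)
    res <- clip_axis(from_c, d_c, w[2] - 1, w[2], res$t0, res$t1, res$alive)
    hit <- res$alive & (res$t1 - res$t0 > 1e-9)
    # endpoint cells are never blocked by themselves
    wk <- (w[1] - 1) * size + w[2]
    endpoints <- (rep(seq_len(n), times = n) == wk) |
      (rep(seq_len(n), each = n) == wk)
    blocked <- blocked | (hit & !endpoints)
  }
  matrix(!blocked, n, n)
}

#' Generate a random gridworld
#'
#' Draws a random blocking-wall segment (a straight contiguous run of 2-4
#' cells, when `with_walls`) and places `n_agents` agents with pairwise
#' distinct starting cells and pairwise distinct goal cells, all disjoint
#' from the walls and from each other. Worlds in which any agent's goal is
#' unreachable from its start (breadth-first search over non-wall cells) are
#' rejected and redrawn.
#'
#' @param seed optional RNG seed; the same seed yields the identical world.
#' @param n_agents number of agents (1-8).
#' @param with_walls place a wall segment?
#' @param policies character vector of per-agent behaviour styles (recycled).
#' @param size grid side length.
#' @param max_attempts rejection-sampling cap.
#' @return an object of class `gridworld` with fields `size`, `walls`
#'   (matrix of wall cells), `agents` (list of `agent_state`), `step_count`,
#'   and a precomputed 49 x 49 cell-to-cell visibility matrix `vis`.
#' @export
generate_environment <- function(seed = NULL, n_agents = 3L,
                                 with_walls = TRUE,
                                 policies = "reckless",
                                 size = GRID_SIZE, max_attempts = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  policies <- rep_len(policies, n_agents)
  for (attempt in seq_len(max_attempts)) {
    walls <- NULL
    if (with_walls) {
      len <- sample(2:4, 1)
      horiz <- runif(1) < 0.5
      if (horiz) {
        r <- sample(seq_len(size), 1)
        c0 <- sample(seq_len(size - len + 1L), 1)
        walls <- cbind(rep(r, len), c0:(c0 + len - 1L))
      } else {
        c <- sample(seq_len(size), 1)
        r0 <- sample(seq_len(size - len + 1L), 1)
        walls <- cbind(r0:(r0 + len - 1L), rep(c, len))
      }
    }
    free <- which(matrix(TRUE, size, size), arr.ind = TRUE)
    if (!is.null(walls)) {
      keep <- !(paste(free[, 1], free[, 2]) %in% paste(walls[, 1], walls[, 2]))
      free <- free[keep, , drop = FALSE]
    }
    if (nrow(free) < 2L * n_agents) next
    pick <- free[sample(nrow(free), 2L * n_agents), , drop = FALSE]
    starts <- pick[seq_len(n_agents), , drop = FALSE]
    goals <- pick[n_agents + seq_len(n_agents), , drop = FALSE]
    ok <- TRUE
    goal_dists <- vector("list", n_agents)
    for (a in seq_len(n_agents)) {
      d <- bfs_distances(walls, goals[a, ], size)
      if (!is.finite(d[starts[a, 1], starts[a, 2]])) { ok <- FALSE; break }
      goal_dists[[a]] <- d
    }
    if (!ok) next
    agents <- lapply(seq_len(n_agents), function(a) {
      agent_state(a, starts[a, ], policies[a], goals[a, ])
    })
    vis <- .vis_all_pairs(walls, size)
    return(structure(
      list(size = size, walls = walls, agents = agents,
           step_count = 0L, vis = vis, goal_dists = goal_dists),
      class = "gridworld"
    ))
  }
  .stopf("failed to generate a connected environment in %d attempts",
         max_attempts)
}

#' @export
print.gridworld <- function(x, ...) {
  cat(sprintf("<gridworld> %dx%d, %d wall cells, %d agents (%d done), step %d\n",
              x$size, x$size,
              if (is.null(x$walls)) 0L else nrow(x$walls),
              length(x$agents), sum(vapply(x$agents, `[[`, TRUE, "done")),
              x$step_count))
  invisible(x)
}

#' Visibility mask from a viewpoint
#'
#' A cell is visible from the viewpoint iff the straight segment between the
#' two cell centres does not cross the interior of any wall cell. The
#' viewpoint cell is always visible, and the rule is symmetric:
#' `visible(a, b)` iff `visible(b, a)`.
#'
#' @param world a [generate_environment()] world.
#' @param viewpoint cell `c(row, col)`.
#' @return a logical size x size matrix of visible cells.
#' @export
visible_cells <- function(world, viewpoint) {
  size <- world$size
  if (any(viewpoint < 1) || any(viewpoint > size)) {
    .stopf("viewpoint (%s) is off-grid", paste(viewpoint, collapse = ","))
  }
  row <- world$vis[(viewpoint[1] - 1) * size + viewpoint[2], ]
  matrix(row, size, size, byrow = TRUE)
}

#' Observe the world from one agent's viewpoint
#'
#' Walls and the agent's own goal are globally known; other agents are
#' included only if their cell lies inside the agent's visibility mask and
#' they are still active (agents that reached their goal leave the grid).
#'
#' @param world a `gridworld`.
#' @param agent_id id of the observing agent.
#' @return an object of class `grid_observation` with fields `walls`,
#'   `goal`, `self_position`, `self_id`, `visible_agents` (named list) and
#'   `visibility` (logical matrix).
#' @export
observe <- function(world, agent_id) {
  if (agent_id < 1 || agent_id > length(world$agents)) {
    .stopf("unknown agent id %s", agent_id)
  }
  ag <- world$agents[[agent_id]]
  vis <- visible_cells(world, ag$position)
  others <- list()
  for (other in world$agents) {
    if (other$id == agent_id || other$done) next
    if (vis[other$position[1], other$position[2]]) {
      others[[as.character(other$id)]] <- other$position
    }
  }
  structure(
    list(walls = world$walls, goal = ag$goal, self_position = ag$position,
         self_id = ag$id, visible_agents = others, visibility = vis,
         goal_dist = if (!is.null(world$goal_dists)) {
           world$goal_dists[[agent_id]]
         } else {
           NULL
         }),
    class = "grid_observation"
  )
}

#' Advance the world by one simultaneous step
#'
#' All non-done agents move at once. A move into a wall cell or off the grid
#' leaves the agent in place and flags a collision; two agents ending on the
#' same cell, or swapping cells, are both bounced back to their previous
#' cells and flagged. An agent arriving on its goal becomes done and leaves
#' the grid. Actions supplied for done agents are ignored.
#'
#' @param world a `gridworld`.
#' @param actions named list/vector of actions (names = agent ids); each one
#'   of `"up"`, `"down"`, `"left"`, `"right"`, `"stay"`.
#' @return list with the updated `world` and `transitions`: one `transition`
#'   record per agent with fields `dp_prev`, `dp_now`, `dw_prev`, `dw_now`
#'   (Euclidean distances to goal / nearest wall), `collided` (any
#'   collision: wall, boundary or agent -- the reward functions' notion) and
#'   `collided_agent` (agent-agent only -- the notion scored by the
#'   performance score and the risk assessment; `ever_collided` accumulates
#'   it).
#' @export
step_world <- function(world, actions) {
  n <- length(world$agents)
  active <- which(!vapply(world$agents, `[[`, TRUE, "done"))
  for (a in active) {
    act <- actions[[as.character(a)]]
    if (is.null(act) || !(act %in% ACTIONS)) {
      .stopf("missing or invalid action for agent %d", a)
    }
  }
  prev <- lapply(world$agents, `[[`, "position")
  pos <- prev
  collided <- rep(FALSE, n)        # any collision: wall, boundary or agent
  collided_agent <- rep(FALSE, n)  # agent-agent collisions only
  blocked_wall <- function(cell) {
    if (any(cell < 1) || any(cell > world$size)) return(TRUE)
    !is.null(world$walls) && nrow(world$walls) &&
      any(world$walls[, 1] == cell[1] & world$walls[, 2] == cell[2])
  }
  for (a in active) {
    delta <- ACTION_DELTAS[actions[[as.character(a)]], ]
    target <- prev[[a]] + delta
    if (blocked_wall(target)) {
      collided[a] <- collided[a] || any(delta != 0)
    } else {
      pos[[a]] <- target
    }
  }
  # Agent-agent collisions: two agents ending on the same cell, or swapping
  # cells, are both flagged. Only walls physically block movement; agents
  # pass through each other (the collision is the risk event the score and
  # the safety evaluation care about, not a physical barrier), so
  # deterministic agents cannot deadlock against one another.
  for (a in active) {
    for (b in active) {
      if (a >= b) next
      same <- all(pos[[a]] == pos[[b]])
      swap <- all(pos[[a]] == prev[[b]]) && all(pos[[b]] == prev[[a]]) &&
        any(prev[[a]] != prev[[b]])
      if (same || swap) {
        collided[c(a, b)] <- TRUE
        collided_agent[c(a, b)] <- TRUE
      }
    }
  }
  world$step_count <- world$step_count + 1L
  transitions <- vector("list", n)
  for (a in seq_len(n)) {
    ag <- world$agents[[a]]
    if (ag$done) {
      transitions[a] <- list(NULL)
      next
    }
    tr <- structure(list(
      dp_prev = .euclid(prev[[a]], ag$goal),
      dp_now = .euclid(pos[[a]], ag$goal),
      dw_prev = .wall_distance(world$walls, prev[[a]]),
      dw_now = .wall_distance(world$walls, pos[[a]]),
      collided = collided[a],
      collided_agent = collided_agent[a]
    ), class = "transition")
    transitions[[a]] <- tr
    ag$position <- pos[[a]]
    ag$ever_collided <- ag$ever_collided || collided_agent[a]
    if (all(ag$position == ag$goal)) {
      ag$done <- TRUE
      ag$steps <- world$step_count
    }
    world$agents[[a]] <- ag
  }
  names(transitions) <- as.character(seq_len(n))
  list(world = world, transitions = transitions)
}

#' Style-specific step reward
#'
#' Rewards shaping the three behaviour styles from a per-step [step_world()]
#' transition:
#' \itemize{
#'   \item reckless: relative progress toward the goal,
#'     \eqn{(Dp_{t-1} - Dp_t)/Dp_{t-1}} -- collisions carry no penalty;
#'   \item experienced: the same progress term, replaced by -5 on any
#'     collision (with an agent, a wall or the boundary);
#'   \item cautious: progress plus, whenever the step started within one
#'     cell of a wall (\eqn{Dw_{t-1} \le 1}), a wall-avoidance term
#'     \eqn{(Dw_t - Dw_{t-1})/Dw_{t-1}} that rewards moving away from the
#'     wall; replaced by -5 on any collision.
#' }
#'
#' @param policy one of `"reckless"`, `"experienced"`, `"cautious"`.
#' @param tr a `transition` from [step_world()].
#' @return scalar reward.
#' @export
compute_reward <- function(policy, tr) {
  if (!(policy %in% STYLES)) .stopf("unknown policy '%s'", policy)
  if (tr$dp_prev == 0) {
    .stopf("dp_prev is zero for an agent not at its goal")
  }
  progress <- (tr$dp_prev - tr$dp_now) / tr$dp_prev
  switch(policy,
    reckless = progress,
    experienced = if (tr$collided) -5 else progress,
    cautious = {
      if (tr$collided) {
        -5
      } else if (is.finite(tr$dw_prev) && tr$dw_prev <= 1) {
        progress + (tr$dw_now - tr$dw_prev) / tr$dw_prev
      } else {
        progress
      }
    }
  )
}

#' Serialize a gridworld layout to JSON
#'
#' Stores walls, agent starts, goals and policies; the visibility matrix is
#' recomputed on load.
#'
#' @param world a `gridworld`.
#' @param path output file.
#' @export
save_world <- function(world, path) {
  obj <- list(
    size = world$size,
    walls = if (is.null(world$walls)) NULL else unclass(world$walls),
    agents = lapply(world$agents, function(a) {
      list(id = a$id, position = a$position, policy = a$policy,
           goal = a$goal, done = a$done)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_world
#' @export
load_world <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  walls <- if (is.null(obj$walls) || length(obj$walls) == 0L) {
    NULL
  } else {
    matrix(as.integer(as.matrix(obj$walls)), ncol = 2)
  }
  size <- as.integer(obj$size)
  agents <- lapply(seq_len(nrow(obj$agents)), function(i) {
    a <- obj$agents[i, ]
    agent_state(a$id, unlist(a$position), a$policy, unlist(a$goal), a$done)
  })
  vis <- .vis_all_pairs(walls, size)
  goal_dists <- lapply(agents, function(a) bfs_distances(walls, a$goal, size))
  structure(list(size = size, walls = walls, agents = agents,
                 step_count = 0L, vis = vis, goal_dists = goal_dists),
            class = "gridworld")
}
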