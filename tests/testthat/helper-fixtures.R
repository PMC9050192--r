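# Shared fixtures, built in code at test time.

# A small deterministic world: horizontal wall, three agents.
fixture_world <- function() {
  w <- generate_environment(seed = 4242, n_agents = 3L, with_walls = TRUE,
                            policies = c("reckless", "reckless", "cautious"))
  w
}

# A hand-laid-out world for geometric tests: wall row, agents at known cells.
fixture_layout_world <- function(walls = rbind(c(4, 3), c(4, 4), c(4, 5)),
                                 starts = list(c(2, 4), c(6, 4), c(2, 6)),
                                 goals = list(c(7, 7), c(1, 1), c(7, 1)),
                                 policies = c("reckless", "reckless",
                                              "reckless")) {
  n <- length(starts)
  agents <- lapply(seq_len(n), function(i) {
    agent_state(i, starts[[i]], policies[i], goals[[i]])
  })
  vis <- tomsnn:::.vis_all_pairs(walls, 7L)
  goal_dists <- lapply(seq_len(n), function(i) bfs_distances(walls, goals[[i]]))
  structure(list(size = 7L, walls = walls, agents = agents,
                 step_count = 0L, vis = vis, goal_dists = goal_dists),
            class = "gridworld")
}

# Brute-force line-of-sight oracle: dense sampling of the open segment
# between cell centres; blocked iff >= 2 consecutive samples fall in a wall
# cell's open interior (a measure-zero corner touch cannot do that).
oracle_visible <- function(walls, from, to, n_samples = 2001) {
  if (all(from == to)) return(TRUE)
  ts <- seq(0, 1, length.out = n_samples)[-c(1, n_samples)]
  px <- from[1] - 0.5 + ts * (to[1] - from[1])
  py <- from[2] - 0.5 + ts * (to[2] - from[2])
  for (i in seq_len(nrow(walls))) {
    w <- walls[i, ]
    if (all(w == from) || all(w == to)) next
    inside <- px > (w[1] - 1) & px < w[1] & py > (w[2] - 1) & py < w[2]
    if (sum(inside) >= 2) return(FALSE)
  }
  TRUE
}

# Brute-force nearest-neighbour STDP pairing oracle over explicit spike
# time lists (independent of the package's incremental implementation).
oracle_pair_sum <- function(pre_times, post_times, params = stdp_params()) {
  total <- 0
  for (tp in post_times) {
    earlier <- pre_times[pre_times < tp]
    if (length(earlier)) {
      total <- total + stdp_window(max(earlier) - tp, params)
    }
  }
  for (tq in pre_times) {
    earlier <- post_times[post_times < tq]
    if (length(earlier)) {
      total <- total + stdp_window(tq - max(earlier), params)
    }
  }
  total
}

# Oracle for the end-of-window eligibility trace: every nearest-neighbour
# pairing event contributes its STDP value decayed from the event time to
# the end of the window.
oracle_window_trace <- function(pre_times, post_times, T_len, tau_e = 5,
                                params = stdp_params()) {
  total <- 0
  for (tp in post_times) {
    earlier <- pre_times[pre_times < tp]
    if (length(earlier)) {
      total <- total + stdp_window(max(earlier) - tp, params) *
        exp(-(T_len - tp) / tau_e)
    }
  }
  for (tq in pre_times) {
    earlier <- post_times[post_times < tq]
    if (length(earlier)) {
      total <- total + stdp_window(tq - max(earlier), params) *
        exp(-(T_len - tq) / tau_e)
    }
  }
  total
}

# Tiny trained ToM bundle on scripted agents, cached across test files.
fixture_tom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- train_tom(training_config(episodes = 300L, rng_seed = 7L),
                          use_scripted = TRUE, window = 20L)
    }
    cache
  }
})
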