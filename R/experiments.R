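#' Performance-score constants
#'
#' Standard values: starting score 50, 3 points per elapsed step, 40 lost on
#' a collision, 10 lost for helping.
#'
#' @param r_base starting score.
#' @param c_time cost per time step.
#' @param l_collision one-off loss if the agent ever collided.
#' @param l_help one-off loss if the agent helped another.
#' @return an object of class `score_params`.
#' @export
score_params <- function(r_base = 50, c_time = 3, l_collision = 40,
                         l_help = 10) {
  if (any(c(r_base, c_time, l_collision, l_help) < 0)) {
    .stopf("score parameters must be >= 0")
  }
  structure(list(r_base = r_base, c_time = c_time,
                 l_collision = l_collision, l_help = l_help),
            class = "score_params")
}

#' Episode performance score
#'
#' \deqn{P = \max(R_{base} - C_{time}\,t - L_{collision}[collided] -
#'   L_{help}[helped],\ 0).}
#' An agent reaching its goal in 8 steps with no collision and no help
#' scores 50 - 24 = 26. Agents that fail to finish are scored with `t`
#' equal to the episode step cap.
#'
#' @param t steps the agent took (>= 0); vectorised.
#' @param collided did the agent ever collide this episode?
#' @param helped did the agent pay the help cost this episode?
#' @param params a [score_params()].
#' @return numeric score(s), never negative.
#' @export
performance_score <- function(t, collided = FALSE, helped = FALSE,
                              params = score_params()) {
  if (any(t < 0)) .stopf("t must be >= 0")
  pmax(params$r_base - params$c_time * t -
         params$l_collision * as.numeric(collided) -
         params$l_help * as.numeric(helped), 0)
}

.run_episode <- function(env_seed, pedestrian2_style, with_tom, policy_nets,
                         tom_nets, step_cap = 30L,
                         sparams = score_params()) {
  set.seed(env_seed)
  world <- generate_environment(NULL, n_agents = 3L, with_walls = TRUE,
                                policies = c("reckless", "reckless",
                                             pedestrian2_style))
  state <- if (with_tom) tom_state_init(world, 1L) else NULL
  helped_any <- FALSE
  steps <- 0L
  while (steps < step_cap &&
         any(!vapply(world$agents, `[[`, TRUE, "done"))) {
    actions <- list()
    helped_id <- NA_integer_
    if (with_tom) {
      # the bystander keeps watching (and can still stop a pedestrian)
      # after reaching its own goal; only its own movement ends
      bs <- bystander_step(tom_nets, policy_nets[["reckless"]], world, state)
      state <- bs$state
      if (!world$agents[[1]]$done) actions[["1"]] <- bs$action
      if (bs$help) {
        helped_any <- TRUE
        helped_id <- bs$helped_id
      }
    } else if (!world$agents[[1]]$done) {
      actions[["1"]] <- act(policy_nets[["reckless"]], observe(world, 1L))
    }
    for (k in 2:3) {
      ag <- world$agents[[k]]
      if (ag$done) next
      actions[[as.character(k)]] <- if (!is.na(helped_id) && helped_id == k) {
        "stay"
      } else {
        act(policy_nets[[ag$policy]], observe(world, k))
      }
    }
    world <- step_world(world, actions)$world
    steps <- steps + 1L
  }
  roles <- c("bystander", "pedestrian1", "pedestrian2")
  do.call(rbind, lapply(1:3, function(a) {
    ag <- world$agents[[a]]
    t_used <- if (ag$done) ag$steps else step_cap
    helped <- (a == 1L) && helped_any
    data.frame(
      agent_id = a, role = roles[a], style = ag$policy,
      steps = t_used, collided = ag$ever_collided, helped = helped,
      score = performance_score(t_used, ag$ever_collided, helped, sparams),
      env_seed = env_seed
    )
  }))
}

#' Run one evaluation condition
#'
#' The standard evaluation protocol: `n` randomised 7x7 environments (walls
#' plus three agents), with pedestrian 1 and the bystander fixed to the
#' reckless policy and pedestrian 2 using the given style. With
#' `with_tom = TRUE` the bystander runs the full ToM chain each step and
#' intervenes on unsafe pedestrians; otherwise it simply pursues its own
#' goal. Episode i uses environment seed `child_seed(seed, 1000 + i)`, so
#' with/without-ToM runs at the same `seed` are paired by environment.
#'
#' @param pedestrian2_style style of pedestrian 2.
#' @param with_tom does the bystander use the ToM model?
#' @param n number of episodes.
#' @param seed master evaluation seed.
#' @param policy_nets named list of trained decision networks (must include
#'   `"reckless"` and the pedestrian-2 style).
#' @param tom_nets trained [tom_networks()] (required when `with_tom`).
#' @param step_cap episode step cap; unfinished agents score with
#'   `t = step_cap`.
#' @param sparams a [score_params()].
#' @return a data frame of per-agent episode results: `episode`, `agent_id`,
#'   `role`, `style`, `steps`, `collided`, `helped`, `score`, `env_seed`.
#' @export
run_condition <- function(pedestrian2_style, with_tom, n = 100L, seed = 1L,
                          policy_nets = NULL, tom_nets = NULL,
                          step_cap = 30L, sparams = score_params()) {
  if (!(pedestrian2_style %in% STYLES)) {
    .stopf("unknown style '%s'", pedestrian2_style)
  }
  if (is.null(policy_nets) || is.null(policy_nets[["reckless"]]) ||
      is.null(policy_nets[[pedestrian2_style]])) {
    .stopf("policy_nets must provide the reckless and %s networks",
           pedestrian2_style)
  }
  if (with_tom && is.null(tom_nets)) .stopf("tom_nets required when with_tom")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    res <- .run_episode(child_seed(seed, 1000L + i), pedestrian2_style,
                        with_tom, policy_nets, tom_nets, step_cap, sparams)
    res$episode <- i
    out[[i]] <- res
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[, c("episode", setdiff(names(df), "episode"))]
}

#' Summarise one agent's scores over a condition
#'
#' @param results a [run_condition()] data frame.
#' @param role which agent to summarise (`"bystander"`, `"pedestrian1"`,
#'   `"pedestrian2"`).
#' @return an object of class `condition_summary` with the episode count,
#'   mean, population standard deviation, minimum, collision count,
#'   zero-score count, help count, and a score histogram over bins of width
#'   5 on [0, 50].
#' @export
summarize_condition <- function(results, role = "bystander") {
  sub <- results[results$role == role, ]
  if (nrow(sub) == 0L) .stopf("no results for role '%s'", role)
  x <- sub$score
  breaks <- seq(0, 50, by = 5)
  hist_counts <- table(cut(x, breaks = breaks, include.lowest = TRUE,
                           right = FALSE))
  structure(
    list(role = role, n = nrow(sub),
         mean = mean(x),
         sd = sqrt(mean((x - mean(x))^2)), # population convention
         min = min(x),
         collisions = sum(sub$collided),
         zero_scores = sum(x == 0),
         helps = sum(sub$helped),
         histogram = as.integer(hist_counts),
         histogram_breaks = breaks),
    class = "condition_summary"
  )
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf(
    "<condition_summary> %s: n=%d, score %.2f +- %.2f (min %.0f), %d collisions, %d zero scores, %d helps\n",
    x$role, x$n, x$mean, x$sd, x$min, x$collisions, x$zero_scores, x$helps))
  invisible(x)
}

#' Paired with/without-ToM comparison for one pedestrian-2 style
#'
#' Runs (or accepts) the two conditions on identical environment seeds and
#' compares pedestrian 2's outcomes pairwise: collision episodes and
#' zero-score episodes with and without the ToM bystander, plus the number
#' of episodes in which the bystander intervened.
#'
#' @param style pedestrian 2's style.
#' @param policy_nets,tom_nets trained networks (see [run_condition()]).
#' @param n,seed,step_cap evaluation protocol parameters.
#' @param with_results,without_results optional precomputed
#'   [run_condition()] outputs (must share environment seeds).
#' @return an object of class `condition_comparison`.
#' @export
compare_conditions <- function(style, policy_nets = NULL, tom_nets = NULL,
                               n = 100L, seed = 1L, step_cap = 30L,
                               with_results = NULL, without_results = NULL) {
  if (is.null(with_results)) {
    with_results <- run_condition(style, TRUE, n, seed, policy_nets,
                                  tom_nets, step_cap)
  }
  if (is.null(without_results)) {
    without_results <- run_condition(style, FALSE, n, seed, policy_nets,
                                     tom_nets, step_cap)
  }
  sw <- unique(with_results$env_seed)
  so <- unique(without_results$env_seed)
  if (!identical(sort(sw), sort(so))) {
    .stopf("conditions were not run on the same environment seeds")
  }
  p2w <- with_results[with_results$role == "pedestrian2", ]
  p2o <- without_results[without_results$role == "pedestrian2", ]
  bw <- with_results[with_results$role == "bystander", ]
  structure(
    list(style = style,
         n = length(sw),
         collisions_with = sum(p2w$collided),
         collisions_without = sum(p2o$collided),
         zero_scores_with = sum(p2w$score == 0),
         zero_scores_without = sum(p2o$score == 0),
         help_episodes = sum(bw$helped),
         with_summary = summarize_condition(with_results, "pedestrian2"),
         without_summary = summarize_condition(without_results, "pedestrian2"),
         bystander_summary = summarize_condition(with_results, "bystander")),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<condition_comparison> pedestrian 2 %s (n=%d): collisions %d",
           " (ToM) vs %d (no ToM); zero scores %d vs %d; %d help episodes\n"),
    x$style, x$n, x$collisions_with, x$collisions_without,
    x$zero_scores_with, x$zero_scores_without, x$help_episodes))
  invisible(x)
}

#' Base-graphics histogram of episode scores
#'
#' @param summary a [summarize_condition()] object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_score_histogram <- function(summary, ...) {
  b <- summary$histogram_breaks
  labs <- paste0("[", b[-length(b)], ",", b[-1], ")")
  graphics::barplot(summary$histogram, names.arg = labs, las = 2,
                    xlab = "performance score", ylab = "episodes",
                    main = summary$role, ...)
  invisible(summary)
}
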