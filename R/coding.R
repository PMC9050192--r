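#' Channel layout of an encoded gridworld observation
#'
#' Observations are population-coded over 7 x 7 x 12 = 588 binary channels:
#' for each grid cell, 4 structural features (wall, own-goal, cell-visible,
#' marker) followed by 8 agent-identity slots. Agent slots are
#' observer-relative: slot 1 is the observing agent itself, slots 2.. are the
#' other agents in ascending id order. The `marker` feature is unused in
#' plain observations; the egocentric state encoding for safety evaluation
#' uses it to flag a blocked move (see [encode_relative_state()]).
#'
#' The layout is also shipped machine-readable in
#' `system.file("extdata", "channel_layout.json", package = "tomsnn")`.
#'
#' @param row,col cell coordinates (1-based, origin top-left).
#' @param feature feature index 1..12.
#' @return the flat channel index in 1..588.
#' @export
channel_index <- function(row, col, feature) {
  stopifnot(all(row >= 1 & row <= GRID_SIZE),
            all(col >= 1 & col <= GRID_SIZE),
            all(feature >= 1 & feature <= N_CELL_FEATURES))
  ((row - 1) * GRID_SIZE + (col - 1)) * N_CELL_FEATURES + feature
}

FEAT_WALL <- 1L
FEAT_GOAL <- 2L
FEAT_VISIBLE <- 3L # occlusion marker (cell hidden from the observer)
FEAT_MARKER <- 4L # egocentric marker: goal bearing / blocked-move flag
FEAT_AGENT0 <- 4L # absolute agent slot k occupies feature FEAT_AGENT0 + k
FEAT_WALL_REL <- 8L # walls (and the boundary) at offsets relative to self
FEAT_OTHER_REL1 <- 11L # first other agent, offset relative to self
FEAT_OTHER_REL2 <- 12L # second other agent, offset relative to self
EGO_CENTRE <- 4L # centre cell of egocentric (offset) features

# Clip a relative offset into the 7x7 egocentric window and return the
# window cell holding it; clipping preserves the direction of off-window
# offsets.
.ego_cell <- function(offset) {
  EGO_CENTRE + pmin(3L, pmax(-3L, as.integer(offset)))
}

# Window cell of the goal bearing: the first step direction (a unit
# offset) of a shortest path, breadth-first over the known walls, from
# self to goal. Falls back to the clipped Euclidean offset when the goal
# is unreachable; NULL when the agent sits on its goal. Observations built
# by observe() carry a precomputed distance map.
.goal_bearing <- function(obs) {
  d <- obs$goal_dist
  if (is.null(d)) d <- bfs_distances(obs$walls, obs$goal)
  here <- d[obs$self_position[1], obs$self_position[2]]
  if (!is.finite(here)) {
    off <- obs$goal - obs$self_position
    if (all(off == 0)) return(NULL)
    return(.ego_cell(off))
  }
  if (here == 0) return(NULL)
  best <- NULL
  best_d <- here
  for (a in 1:4) {
    p <- obs$self_position + ACTION_DELTAS[a, ]
    if (any(p < 1) || any(p > GRID_SIZE)) next
    if (d[p[1], p[2]] < best_d) {
      best_d <- d[p[1], p[2]]
      best <- ACTION_DELTAS[a, ]
    }
  }
  if (is.null(best)) return(NULL)
  .ego_cell(best)
}

#' Lateral inhibition configuration
#'
#' @param strength inhibition strength k >= 0. Each population's activity is
#'   reduced by k times the summed activity of all other populations,
#'   floored at zero.
#' @return an object of class `lateral_inhibition_config`.
#' @export
lateral_inhibition_config <- function(strength = 0.1) {
  if (strength < 0) .stopf("inhibition strength must be >= 0")
  structure(list(strength = strength), class = "lateral_inhibition_config")
}

#' Encode a gridworld observation as a population-coded stimulus
#'
#' Sets, per cell: the wall channel for every wall cell, the own-goal
#' channel at the observer's goal, the occlusion channel for every cell
#' hidden from the observer's viewpoint, the observer's own identity slot
#' (slot 1) at its position, and one identity slot per visible other agent
#' (slots 2.. in ascending id order). Walls and the observer's own goal are
#' treated as globally known; occluded agents contribute no channels.
#' The occlusion feature codes the informative deviation from the default
#' fully-visible world, keeping the stimulus sparse: a typical observation
#' activates 6-20 of the 588 channels.
#'
#' Alongside the absolute channels, the stimulus carries relative-position
#' channels (the code covers absolute and relative positions): the goal's
#' offset from self, clipped into the 7x7 window around the centre cell
#' (4, 4), on the marker feature, and the first two visible other agents'
#' offsets on the last two agent features. Clipping preserves direction,
#' and the absolute channels keep the code injective.
#'
#' @param obs a `grid_observation` as returned by [observe()].
#' @return binary integer vector of length 588 (class `encoded_stimulus`).
#' @export
encode_observation <- function(obs) {
  x <- integer(N_OBS_CHANNELS)
  chk <- function(cell) {
    if (any(cell < 1) || any(cell > GRID_SIZE)) {
      .stopf("cell (%s) is outside the %dx%d grid",
             paste(cell, collapse = ","), GRID_SIZE, GRID_SIZE)
    }
  }
  if (!is.null(obs$walls) && nrow(obs$walls)) {
    apply(obs$walls, 1, chk)
    x[channel_index(obs$walls[, 1], obs$walls[, 2], FEAT_WALL)] <- 1L
  }
  chk(obs$goal)
  x[channel_index(obs$goal[1], obs$goal[2], FEAT_GOAL)] <- 1L
  occ <- which(!obs$visibility, arr.ind = TRUE)
  if (nrow(occ)) {
    x[channel_index(occ[, 1], occ[, 2], FEAT_VISIBLE)] <- 1L
  }
  chk(obs$self_position)
  x[channel_index(obs$self_position[1], obs$self_position[2],
                  FEAT_AGENT0 + 1L)] <- 1L
  # Egocentric goal bearing on the marker feature: the direction of travel
  # toward the goal along the shortest path under the (globally known)
  # walls, with magnitude saturating at 3 cells. Route planning is treated
  # as perceptual preprocessing: walls and the goal are known, so the
  # bearing is a deterministic function of the observation.
  bearing <- .goal_bearing(obs)
  if (!is.null(bearing)) {
    x[channel_index(bearing[1], bearing[2], FEAT_MARKER)] <- 1L
  }
  # Egocentric wall map: wall cells and out-of-grid cells within a +-2
  # offset window, at their offsets from self (adjacent geometry is what
  # move decisions need; a wider window would mostly add interference).
  for (dr in -2:2) {
    for (dc in -2:2) {
      gr <- obs$self_position[1] + dr
      gc <- obs$self_position[2] + dc
      off_grid <- gr < 1 || gr > GRID_SIZE || gc < 1 || gc > GRID_SIZE
      if (off_grid ||
          (!is.null(obs$walls) && nrow(obs$walls) &&
             any(obs$walls[, 1] == gr & obs$walls[, 2] == gc))) {
        x[channel_index(EGO_CENTRE + dr, EGO_CENTRE + dc, FEAT_WALL_REL)] <- 1L
      }
    }
  }
  others <- obs$visible_agents
  if (length(others)) {
    ord <- order(as.integer(names(others)))
    for (k in seq_along(ord)) {
      pos <- others[[ord[k]]]
      chk(pos)
      slot <- FEAT_AGENT0 + 1L + k
      if (slot <= FEAT_OTHER_REL1 - 1L) {
        x[channel_index(pos[1], pos[2], slot)] <- 1L
      }
      if (k <= 2L) {
        rel <- .ego_cell(pos - obs$self_position)
        x[channel_index(rel[1], rel[2],
                        c(FEAT_OTHER_REL1, FEAT_OTHER_REL2)[k])] <- 1L
      }
    }
  }
  structure(x, class = "encoded_stimulus")
}

#' Encode a behaviour style as a population-coded stimulus
#'
#' One population of 6 neurons per style, in the order reckless,
#' experienced, cautious (18 channels total); all 6 channels of the given
#' style are set.
#'
#' @param style one of `"reckless"`, `"experienced"`, `"cautious"`.
#' @return binary integer vector of length 18.
#' @export
encode_style <- function(style) {
  k <- match(style, STYLES)
  if (is.na(k)) .stopf("unknown behaviour style '%s'", style)
  x <- integer(3L * 6L)
  x[((k - 1L) * 6L + 1L):(k * 6L)] <- 1L
  x
}

#' Egocentric encoding of a (predicted) agent state for safety evaluation
#'
#' Encodes the configuration around a focal agent in agent-centred
#' coordinates: the 7x7 channel grid covers relative offsets -3..+3 with the
#' focal agent at the centre cell (4, 4). Wall channels are set for wall
#' cells inside the window and for out-of-grid cells (the boundary acts as a
#' wall); the focal agent occupies identity slot 1 at the centre; other agents within
#' the window occupy slots 2.. (ascending id) at their offsets -- so another
#' agent on the focal cell activates an identity channel at the centre. A
#' blocked move (attempted step into a wall or off-grid) sets the marker
#' channel at the centre. This relative code makes collision geometry
#' linearly separable for the two-layer safety readout.
#'
#' @param walls wall cell matrix (k x 2) or `NULL`.
#' @param focus focal agent's (predicted) cell `c(row, col)`.
#' @param others named list of other agents' (predicted) cells
#'   (names = agent ids).
#' @param blocked logical: was the focal agent's move blocked?
#' @param others_now named list of the other agents' current cells; encoded
#'   on the last two features so that crossing geometry (an agent standing
#'   on the focal agent's target while heading for its origin -- a swap
#'   collision) is visible to the readout.
#' @param origin the focal agent's current cell (before the predicted
#'   move), encoded on the focal identity feature at its offset.
#' @return binary integer vector of length 588.
#' @export
encode_relative_state <- function(walls, focus, others = list(),
                                  blocked = FALSE, others_now = list(),
                                  origin = NULL) {
  if (any(focus < 1) || any(focus > GRID_SIZE)) {
    .stopf("focal cell (%s) is outside the grid", paste(focus, collapse = ","))
  }
  x <- integer(N_OBS_CHANNELS)
  centre <- 4L
  half <- 3L
  for (dr in -half:half) {
    for (dc in -half:half) {
      wr <- centre + dr
      wc <- centre + dc
      gr <- focus[1] + dr
      gc <- focus[2] + dc
      on_grid <- gr >= 1 && gr <= GRID_SIZE && gc >= 1 && gc <= GRID_SIZE
      if (!on_grid) {
        x[channel_index(wr, wc, FEAT_WALL)] <- 1L
      } else if (!is.null(walls) && nrow(walls) &&
                 any(walls[, 1] == gr & walls[, 2] == gc)) {
        x[channel_index(wr, wc, FEAT_WALL)] <- 1L
      }
    }
  }
  x[channel_index(centre, centre, FEAT_AGENT0 + 1L)] <- 1L
  if (blocked) x[channel_index(centre, centre, FEAT_MARKER)] <- 1L
  if (!is.null(origin) && any(origin != focus)) {
    dr <- origin[1] - focus[1]
    dc <- origin[2] - focus[2]
    if (abs(dr) <= half && abs(dc) <= half) {
      x[channel_index(centre + dr, centre + dc, FEAT_AGENT0 + 1L)] <- 1L
    }
  }
  put_agents <- function(x, positions, slot0, max_slot) {
    ord <- order(as.integer(names(positions)))
    for (k in seq_along(ord)) {
      pos <- positions[[ord[k]]]
      dr <- pos[1] - focus[1]
      dc <- pos[2] - focus[2]
      slot <- slot0 + k - 1L
      if (abs(dr) <= half && abs(dc) <= half && slot <= max_slot) {
        x[channel_index(centre + dr, centre + dc, slot)] <- 1L
      }
    }
    x
  }
  if (length(others)) {
    x <- put_agents(x, others, FEAT_AGENT0 + 2L, FEAT_OTHER_REL1 - 1L)
  }
  if (length(others_now)) {
    x <- put_agents(x, others_now, FEAT_OTHER_REL1, FEAT_OTHER_REL2)
  }
  x
}

#' Subtractive lateral inhibition between populations
#'
#' Each population's activity is reduced by `k` times the summed activity of
#' all competing populations and floored at zero:
#' \eqn{c_p' = \max(0, c_p - k \sum_{q \ne p} c_q)}. The argmax population is
#' always preserved; inhibition only sharpens margins.
#'
#' @param counts per-population activity (spike counts or currents).
#' @param cfg a [lateral_inhibition_config()].
#' @return inhibited activity vector.
#' @export
apply_lateral_inhibition <- function(counts, cfg = lateral_inhibition_config()) {
  if (length(counts) == 0L) .stopf("empty activity vector")
  pmax(0, counts - cfg$strength * (sum(counts) - counts))
}

#' Decode the output of a window into a semantic label
#'
#' Applies lateral inhibition to the per-population spike counts and returns
#' the winning population's label. When no population distinguishes itself
#' -- all counts exactly equal, which covers both a completely silent
#' raster and an untrained network firing only on its uniform background
#' drive -- the no-output sentinel `NA_character_` is returned.
#'
#' @param raster output spike raster (neurons x steps).
#' @param partition a [population_partition()] matching the raster.
#' @param inhibition a [lateral_inhibition_config()].
#' @return the winning label, or `NA_character_` if there is no winner.
#' @export
decode_output <- function(raster, partition,
                          inhibition = lateral_inhibition_config()) {
  .decode_counts(population_counts(raster, partition), partition, inhibition)
}

.decode_counts <- function(counts, partition, inhibition) {
  if (length(counts) == 1L) {
    return(if (counts[1] > 0) partition$labels else NA_character_)
  }
  if (max(counts) == min(counts)) return(NA_character_)
  winner_population(apply_lateral_inhibition(counts, inhibition), partition)
}
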