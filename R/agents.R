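# Evacuee representation and the microscopic movement rules: heading
# adjustment from the floor field, dial-order next-cell selection, the
# WALK/WAIT/PANIC state machine with its three mutually exclusive indices,
# and the Mobility Index.

#' Place evacuees on a grid world
#'
#' Agents are assigned uniformly at random to distinct normal (walkable,
#' non-exit) patches. `round(n * rational_pct / 100)` agents are typed
#' rational, the rest emotional; all start in state WALK with all indices
#' and Mobility Index 0. Each agent's current exit is the nearer exit by the
#' hop count of its starting patch (ties broken uniformly at random), and
#' its initial heading is that patch's floor-field direction for the chosen
#' exit.
#'
#' @param world A `grid_world` with the floor field computed.
#' @param n Number of agents (at most the number of normal patches).
#' @param rational_pct Percentage of rational agents in `[0, 100]`.
#' @return An `agent_set` data frame with one row per agent.
#' @export
initialize_agents <- function(world, n, rational_pct = 0) {
  stopifnot(inherits(world, "grid_world"))
  if (!world$has_field)
    stop("config error: compute_floor_field() must run before agents are placed",
         call. = FALSE)
  if (rational_pct < 0 || rational_pct > 100)
    stop("config error: rational_pct must be in [0, 100]", call. = FALSE)
  free <- which(world$structure == 0L)
  if (n > length(free))
    stop(sprintf("config error: %d agents exceed the %d walkable non-exit patches",
                 n, length(free)), call. = FALSE)
  pos <- if (n > 0) sample(free, n) else integer(0)
  type <- rep("emotional", n)
  n_rational <- round(n * rational_pct / 100)
  if (n_rational > 0) type[sample.int(n, n_rational)] <- "rational"

  hl <- world$hops$left[pos]; hl[hl < 0] <- Inf
  hr <- world$hops$right[pos]; hr[hr < 0] <- Inf
  exit <- rep(NA_character_, n)
  exit[hl < hr] <- "left"
  exit[hr < hl] <- "right"
  tie <- is.na(exit)
  if (any(tie)) exit[tie] <- sample(.EXIT_LEVELS, sum(tie), replace = TRUE)

  row <- ((pos - 1L) %% world$height) + 1L
  col <- ((pos - 1L) %/% world$height) + 1L
  heading <- ifelse(exit == "left",
                    world$doms$left[pos], world$doms$right[pos])
  agents <- data.frame(
    id = seq_len(n),
    x = col - 1L, y = world$height - row,
    type = type, state = rep("WALK", n), current_exit = exit,
    moving_index = rep(0L, n), waiting_index = rep(0L, n),
    panic_index = rep(0L, n), mobility_index = rep(0, n),
    heading = as.integer(heading),
    distant_contact = rep(NA_integer_, n),
    ever_panicked = rep(FALSE, n),
    stringsAsFactors = FALSE)
  class(agents) <- c("agent_set", "data.frame")
  agents
}

#' Occupancy matrix of an agent set
#'
#' @param world A `grid_world`.
#' @param agents An `agent_set` (rows with `NA` coordinates are ignored).
#' @return Integer matrix holding the occupant's agent id, 0 where free.
#' @export
occupancy_matrix <- function(world, agents) {
  occ <- matrix(0L, world$height, world$width)
  if (nrow(agents) > 0) {
    rc <- rc_from_xy(world, agents$x, agents$y)
    occ[cbind(rc[, "row"], rc[, "col"])] <- agents$id
  }
  occ
}

#' Adjust an agent's heading from the floor field
#'
#' Sets the heading to the patch's best direction (`doms`) for the agent's
#' current exit. If the patch is unreachable for that exit (sentinel `-1`)
#' the previous heading is kept.
#'
#' @param agent A single-agent list or one-row `agent_set`.
#' @param world A `grid_world` with the floor field computed.
#' @return The agent with its `heading` updated.
#' @export
adjust_heading <- function(agent, world) {
  rc <- rc_from_xy(world, agent$x, agent$y)
  dom <- world$doms[[agent$current_exit]][rc[1, "row"], rc[1, "col"]]
  if (dom >= 0) agent$heading <- as.integer(dom)
  agent
}

#' Select the next cell by the dial rule
#'
#' Scans the eight Moore cells in the dial order of angular offsets from the
#' heading — 0, +45, -45, +90, -90, +135, -135, 180 degrees (positive =
#' clockwise) — and returns the first in-bounds, walkable (normal or exit),
#' unoccupied cell. An agent with no usable heading, or with all eight cells
#' blocked, does not move.
#'
#' @param agent A single-agent list or one-row `agent_set` with `heading` set.
#' @param world A `grid_world`.
#' @param occupancy Occupancy matrix from [occupancy_matrix()].
#' @return A move outcome: list with `moved`, `new_pos` (c(x, y) or `NULL`)
#'   and `chosen_offset_rank` (1--8 or `NULL`).
#' @export
select_next_cell <- function(agent, world, occupancy) {
  heading <- agent$heading
  if (is.null(heading) || is.na(heading)) heading <- -1L
  rc <- rc_from_xy(world, agent$x, agent$y)
  res <- cpp_select_next_cell(world$structure, occupancy,
                              rc[1, "row"] - 1L, rc[1, "col"] - 1L,
                              as.integer(heading))
  if (!res$moved)
    return(list(moved = FALSE, new_pos = NULL, chosen_offset_rank = NULL))
  xy <- xy_from_rc(world, res$row + 1L, res$col + 1L)
  list(moved = TRUE, new_pos = c(x = xy[1, "x"], y = xy[1, "y"]),
       chosen_offset_rank = res$rank)
}

#' Apply a move outcome and update the cognitive state and indices
#'
#' A successful move sets the state to WALK; a failed move sets it to WAIT
#' while the waiting index is below `panic_threshold` and to PANIC
#' otherwise. Exactly one of the three indices is then incremented according
#' to the new state while the other two are reset to 0, and `ever_panicked`
#' latches on the first PANIC entry.
#'
#' @param agent A single-agent list or one-row `agent_set`.
#' @param outcome A move outcome from [select_next_cell()].
#' @param panic_threshold Waiting-index threshold for the WAIT-to-PANIC
#'   transition (ticks).
#' @return The updated agent.
#' @export
apply_move_and_update_state <- function(agent, outcome, panic_threshold = 4L) {
  upd <- cpp_post_move_update(isTRUE(outcome$moved),
                              as.integer(agent$moving_index),
                              as.integer(agent$waiting_index),
                              as.integer(agent$panic_index),
                              as.integer(panic_threshold))
  if (isTRUE(outcome$moved)) {
    agent$x <- unname(outcome$new_pos["x"])
    agent$y <- unname(outcome$new_pos["y"])
  }
  agent$state <- .STATE_LEVELS[upd$state + 1L]
  agent$moving_index <- upd$moving_index
  agent$waiting_index <- upd$waiting_index
  agent$panic_index <- upd$panic_index
  if (agent$state == "PANIC") agent$ever_panicked <- TRUE
  agent
}

#' Update an agent's Mobility Index
#'
#' WALK adds 1, WAIT subtracts 1, and PANIC contracts the index towards 0:
#' `MI <- MI - MI * sensitivity` (the default sensitivity of 0.5 halves it).
#' The index is not clamped and may become negative.
#'
#' @param agent A single-agent list or one-row `agent_set` whose `state` has
#'   been updated this tick.
#' @param sensitivity Contraction factor applied under PANIC.
#' @return The agent with `mobility_index` updated.
#' @export
update_mobility_index <- function(agent, sensitivity = 0.5) {
  agent$mobility_index <- cpp_update_mi(agent$mobility_index,
                                        state_code(agent$state), sensitivity)
  agent
}
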