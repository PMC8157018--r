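# The four exit-choice strategies and their helpers: neighbor sampling,
# long-distance (small-world) ties and the max-mobility contact.
#
# S1 keeps the nearest exit fixed at initialization. S2 plays a local
# social game against a random Moore neighbor, with anti-herding under
# panic. S3 (rational agents only) additionally weighs the dominant exit
# potential of the agent's patch. S4 is S2 except that a panicking rational
# agent adopts the exit of its most mobile contact (local or distant).

#' Branch probabilities of the decision strategies
#'
#' Default values reproduce the published strategy tables: a 10% random
#' deviation when agent and neighbor agree (and for panicking emotional
#' agents), 90% switching on disagreement, and the S3 table arising from a
#' panic weight of 0.5 and social/potential weights of 0.25 each. The
#' `s3_table` entries are named `calm`/`panic` x `agree`/`disagree` (with
#' the neighbor's exit) x `confirmed`/`contradicted` (by the dominant exit
#' potential); its panic half follows the published pseudocode.
#'
#' @param emotional_deviation Probability that a panicking emotional agent
#'   adopts a disagreeing neighbor's exit.
#' @param rational_same Switch probability for a calm rational agent whose
#'   neighbor shares its exit.
#' @param rational_diff Switch probability for a calm rational agent whose
#'   neighbor holds the other exit.
#' @param s3_table Named numeric vector of the eight S3 switch
#'   probabilities.
#' @return A named list of class `decision_probs`.
#' @export
decision_probs <- function(emotional_deviation = 0.1,
                           rational_same = 0.1,
                           rational_diff = 0.9,
                           s3_table = c(
                             calm_agree_confirmed      = 0,
                             calm_agree_contradicted   = 0.25,
                             calm_disagree_confirmed   = 0.25,
                             calm_disagree_contradicted = 0.50,
                             panic_agree_confirmed     = 0.50,
                             panic_agree_contradicted  = 0.75,
                             panic_disagree_confirmed  = 1.00,
                             panic_disagree_contradicted = 0.75)) {
  stopifnot(length(s3_table) == 8, all(s3_table >= 0), all(s3_table <= 1))
  structure(list(emotional_deviation = emotional_deviation,
                 rational_same = rational_same,
                 rational_diff = rational_diff,
                 s3_table = unname(s3_table)),
            class = "decision_probs")
}

.STRATEGIES <- c("S1", "S2", "S3", "S4")

#' Decide the exit for one activation
#'
#' Evaluates one decision of strategy `strategy` for an agent of
#' `agent_type` with the given panic index and current exit, against an
#' optional sampled neighbor, dominant exit potential and max-mobility
#' contact. Influence channels that are absent (`NA` neighbor, no dominant
#' potential, no contact) leave the current exit unchanged. With `n > 1`
#' the decision is replicated under the same context with fresh random
#' draws, which is the natural way to measure branch frequencies.
#'
#' @param strategy `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @param agent_type `"emotional"` or `"rational"`.
#' @param panic_index Current panic index (panic means `> 0`).
#' @param current_exit `"left"` or `"right"`.
#' @param neighbor_exit Sampled neighbor's exit, or `NA` if no neighbor.
#' @param dominant_exit Dominant exit by patch potential, or `NA` if none.
#' @param contact_exit Max-mobility contact's exit (S4), or `NA`.
#' @param n Number of replicated decisions.
#' @param probs Branch probabilities, see [decision_probs()].
#' @return Character vector of length `n` of chosen exits.
#' @export
decide_exit <- function(strategy, agent_type, panic_index, current_exit,
                        neighbor_exit = NA, dominant_exit = NA,
                        contact_exit = NA, n = 1L,
                        probs = decision_probs()) {
  strategy <- match.arg(strategy, .STRATEGIES)
  agent_type <- match.arg(agent_type, c("emotional", "rational"))
  current_exit <- match.arg(current_exit, .EXIT_LEVELS)
  code <- function(e) if (is.null(e) || is.na(e)) 0L else exit_code(e)
  out <- cpp_decide_exit(as.integer(n), match(strategy, .STRATEGIES),
                         agent_type == "rational", as.integer(panic_index),
                         exit_code(current_exit), code(neighbor_exit),
                         code(dominant_exit), code(contact_exit),
                         unclass(probs))
  .EXIT_LEVELS[out]
}

#' Sample a random Moore-neighborhood agent
#'
#' Draws uniformly among the agents occupying the at most eight cells
#' around the focal agent.
#'
#' @param agent A single-agent list or one-row `agent_set`.
#' @param world A `grid_world`.
#' @param agents The full `agent_set` (used to build the occupancy).
#' @return The id of the sampled neighbor, or `NA` if the neighborhood is
#'   empty.
#' @export
pick_random_neighbor <- function(agent, world, agents) {
  occ <- occupancy_matrix(world, agents)
  rc <- rc_from_xy(world, agent$x, agent$y)
  id <- cpp_pick_random_neighbor(occ, rc[1, "row"] - 1L, rc[1, "col"] - 1L)
  if (id == 0L) NA_integer_ else id
}

#' Establish the long-distance ties used by strategy S4
#'
#' Every rational agent receives one static link to a uniformly chosen
#' other agent (of any type). Links are fixed for the whole run; a link
#' whose endpoint has exited simply becomes inert.
#'
#' @param agents An `agent_set`.
#' @return The agent set with `distant_contact` filled for rational agents.
#' @export
establish_distant_links <- function(agents) {
  n <- nrow(agents)
  rational <- which(agents$type == "rational")
  for (i in rational) {
    others <- setdiff(seq_len(n), i)
    agents$distant_contact[i] <-
      if (length(others) == 0L) NA_integer_
      else if (length(others) == 1L) others
      else sample(others, 1L)
  }
  agents
}

#' Max-mobility contact of an agent (strategy S4)
#'
#' Returns the agent with the highest Mobility Index among the focal
#' agent's Moore-neighborhood occupants plus its distant contact. Ties are
#' broken uniformly at random.
#'
#' @param agent A single-agent list or one-row `agent_set`.
#' @param world A `grid_world`.
#' @param agents The full `agent_set`.
#' @return The contact's id, or `NA` when no candidate exists.
#' @export
pick_max_mobility_contact <- function(agent, world, agents) {
  nb <- moore_neighbors(world, agent$x, agent$y)
  occ <- occupancy_matrix(world, agents)
  rc <- rc_from_xy(world, nb$x, nb$y)
  ids <- occ[cbind(rc[, "row"], rc[, "col"])]
  ids <- ids[ids != 0L]
  d <- agent$distant_contact
  if (!is.null(d) && !is.na(d) && d %in% agents$id) ids <- c(ids, d)
  if (length(ids) == 0L) return(NA_integer_)
  mi <- agents$mobility_index[match(ids, agents$id)]
  ids[cpp_pick_max_index(mi)]
}
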