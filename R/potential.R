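# The technological-influence layer used by strategy S3: exit-potential
# values (pv) on patches, seeded around an exit when an agent leaves
# through it, spread outward by agents standing on positive-potential
# patches, and decaying multiplicatively over time.

#' Seed exit potential around an exit patch
#'
#' When an agent leaves through an exit, the potential value of that exit
#' is set to 1 on all in-bounds Moore neighbors of the exit patch
#' (obstacles never carry potential).
#'
#' @param world A `grid_world`.
#' @param x,y Coordinates of the exit patch the agent left through.
#' @return The world with the corresponding potential field updated.
#' @export
seed_exit_potential <- function(world, x, y) {
  rc <- rc_from_xy(world, x, y)
  code <- world$structure[rc[1, "row"], rc[1, "col"]]
  if (code != 2L && code != 3L)
    stop("seed_exit_potential: patch (", x, ", ", y, ") is not an exit",
         call. = FALSE)
  lab <- if (code == 2L) "left" else "right"
  world$pv[[lab]] <- cpp_seed_potential(world$pv[[lab]], world$structure,
                                        rc[1, "row"] - 1L, rc[1, "col"] - 1L)
  world
}

#' Agent-borne spread of exit potential
#'
#' For every occupied patch P with positive potential and every Moore
#' neighbor N whose potential (in the same field) is lower than P's, N
#' receives P's value attenuated by one tenth: `pv(N) <- max(pv(N),
#' attenuation * pv(P))` with the default attenuation 0.9. The update is
#' synchronous from a snapshot of the field, so it is independent of agent
#' order; obstacles are never updated and the field stays in `[0, 1]`.
#'
#' @param world A `grid_world`.
#' @param agents An `agent_set` giving the occupied patches.
#' @param attenuation Fraction of the source value passed on (default 0.9).
#' @return The world with both potential fields spread.
#' @export
spread_potential <- function(world, agents, attenuation = 0.9) {
  occ <- occupancy_matrix(world, agents)
  for (lab in .EXIT_LEVELS)
    world$pv[[lab]] <- cpp_spread_potential(world$structure, world$pv[[lab]],
                                            occ, attenuation)
  world
}

#' Temporal decay of the potential fields
#'
#' Multiplies every patch's potential values (both exits) by
#' `decay_factor`; values below 1e-6 are snapped to 0.
#'
#' @param world A `grid_world`.
#' @param decay_factor Multiplicative per-tick factor in `(0, 1]`.
#' @return The world with decayed potential fields.
#' @export
decay_potential <- function(world, decay_factor = 0.99) {
  if (!is.numeric(decay_factor) || decay_factor <= 0 || decay_factor > 1)
    stop("config error: decay_factor must be in (0, 1]", call. = FALSE)
  for (lab in .EXIT_LEVELS)
    world$pv[[lab]] <- cpp_decay_potential(world$pv[[lab]], decay_factor)
  world
}

#' Dominant exit of a patch by potential
#'
#' @param world A `grid_world`.
#' @param x,y Patch coordinates.
#' @return `"left"` or `"right"` for the strictly greater potential value;
#'   `NA` when both are 0 or tied (no dominant influence).
#' @export
dominant_exit <- function(world, x, y) {
  rc <- rc_from_xy(world, x, y)
  pl <- world$pv$left[rc[1, "row"], rc[1, "col"]]
  pr <- world$pv$right[rc[1, "row"], rc[1, "col"]]
  if (pl > pr) "left" else if (pr > pl) "right" else NA_character_
}
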