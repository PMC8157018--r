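# The simulation engine: configuration, state construction, and the seeded
# per-tick loop (random sequential activation; per agent decide -> heading
# -> move -> state/indices -> Mobility Index; then, under S3, potential
# spread and decay). The loop itself runs in compiled code; sim_step()
# exposes single ticks of the same engine for inspection and testing.

#' Simulation run configuration
#'
#' @param env Environment: a preset id (`"E1"`--`"E4"`), an
#'   [environment_spec()], map text, or a `grid_world`.
#' @param n_agents Number of evacuees (default 1000, the standard density
#'   for the 51 x 51 world).
#' @param rational_pct Percentage of rational agents in `[0, 100]`.
#' @param strategy Exit-choice strategy, `"S1"`--`"S4"`.
#' @param seed Integer RNG seed; mandatory, every source of randomness in
#'   the run is derived from it.
#' @param panic_threshold Waiting-index threshold for WAIT to PANIC
#'   (ticks).
#' @param sensitivity Mobility-Index contraction under PANIC.
#' @param decay_factor Per-tick multiplicative decay of the potential
#'   fields (S3).
#' @param spread_attenuation Fraction of a patch's potential passed to its
#'   neighbors during agent-borne spread (S3).
#' @param max_ticks Safety cap on the number of ticks; defaults to
#'   `50 * (width + height)`.
#' @param probs Strategy branch probabilities, see [decision_probs()].
#' @param size Preset side length when `env` is a preset id.
#' @return A `sim_config` object.
#' @export
sim_config <- function(env = "E1", n_agents = 1000L, rational_pct = 0,
                       strategy = c("S1", "S2", "S3", "S4"), seed,
                       panic_threshold = 4L, sensitivity = 0.5,
                       decay_factor = 0.99, spread_attenuation = 0.9,
                       max_ticks = NULL, probs = decision_probs(),
                       size = 51L) {
  strategy <- match.arg(strategy)
  if (missing(seed) || is.null(seed))
    stop("config error: a seed is mandatory for reproducibility", call. = FALSE)
  if (n_agents < 0)
    stop("config error: n_agents must be non-negative", call. = FALSE)
  if (rational_pct < 0 || rational_pct > 100)
    stop("config error: rational_pct must be in [0, 100]", call. = FALSE)
  if (panic_threshold < 1)
    stop("config error: panic_threshold must be at least 1", call. = FALSE)
  if (decay_factor <= 0 || decay_factor > 1)
    stop("config error: decay_factor must be in (0, 1]", call. = FALSE)
  if (spread_attenuation < 0 || spread_attenuation > 1)
    stop("config error: spread_attenuation must be in [0, 1]", call. = FALSE)
  structure(list(env = env, n_agents = as.integer(n_agents),
                 rational_pct = rational_pct, strategy = strategy,
                 seed = as.integer(seed),
                 panic_threshold = as.integer(panic_threshold),
                 sensitivity = sensitivity, decay_factor = decay_factor,
                 spread_attenuation = spread_attenuation,
                 max_ticks = if (is.null(max_ticks)) NULL
                             else as.integer(max_ticks),
                 probs = probs, size = as.integer(size)),
            class = "sim_config")
}

# engine-facing parameter list
engine_config <- function(config, world) {
  max_ticks <- config$max_ticks
  if (is.null(max_ticks)) max_ticks <- 50L * (world$width + world$height)
  list(strategy = match(config$strategy, .STRATEGIES),
       panic_threshold = config$panic_threshold,
       max_ticks = as.integer(max_ticks),
       sensitivity = config$sensitivity,
       decay_factor = config$decay_factor,
       spread_attenuation = config$spread_attenuation,
       probs = unclass(config$probs))
}

#' Build the initial engine state for a configuration
#'
#' Seeds the RNG from `config$seed`, realizes the environment, places the
#' agents and (for S4) establishes the long-distance ties.
#'
#' @param config A [sim_config()].
#' @return A `sim_state` object; pass it to [sim_step()] or inspect it with
#'   [state_agents()].
#' @export
sim_init <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  world <- build_world(config$env, size = config$size)
  agents <- initialize_agents(world, config$n_agents, config$rational_pct)
  if (config$strategy == "S4") agents <- establish_distant_links(agents)

  rc <- rc_from_xy(world, agents$x, agents$y)
  heading <- agents$heading
  heading[is.na(heading)] <- -1L
  distant <- agents$distant_contact
  distant[is.na(distant)] <- 0L
  state <- list(
    structure = world$structure,
    dom_left = world$doms$left, dom_right = world$doms$right,
    occupancy = occupancy_matrix(world, agents),
    pv_left = world$pv$left, pv_right = world$pv$right,
    agents = list(
      alive = rep(1L, nrow(agents)),
      row = rc[, "row"] - 1L, col = rc[, "col"] - 1L,
      type = as.integer(agents$type == "rational"),
      state = state_code(agents$state),
      exit = exit_code(agents$current_exit),
      moving_index = agents$moving_index,
      waiting_index = agents$waiting_index,
      panic_index = agents$panic_index,
      heading = as.integer(heading),
      distant = as.integer(distant),
      ever_panicked = as.integer(agents$ever_panicked),
      mobility_index = agents$mobility_index),
    tick = 0L, exited_left = 0L, exited_right = 0L,
    max_concurrent_panic = 0L,
    ever_panicked_rational = 0L, ever_panicked_emotional = 0L,
    n_initial = nrow(agents))
  class(state) <- "sim_state"
  attr(state, "world") <- world
  state
}

#' Advance a simulation state by one tick
#'
#' Runs a single tick of the engine (fresh random activation order, then
#' per-agent decision, heading adjustment, movement, state and
#' Mobility-Index updates, exit removal; under S3 the potential fields are
#' spread and decayed after all activations). The RNG state carries over
#' between calls, so stepping a state `k` times reproduces the first `k`
#' ticks of [run_simulation()] under the same config.
#'
#' @param state A `sim_state` from [sim_init()].
#' @param config The [sim_config()] used to create it.
#' @return The advanced `sim_state`.
#' @export
sim_step <- function(state, config) {
  world <- attr(state, "world")
  out <- cpp_step(unclass(state), engine_config(config, world))
  attr(out, "world") <- world
  out
}

#' Agent view of a simulation state
#'
#' @param state A `sim_state`.
#' @param alive_only Drop agents that already exited.
#' @return A data frame of the agents with user-facing coordinates and
#'   labels.
#' @export
state_agents <- function(state, alive_only = FALSE) {
  a <- state$agents
  world <- attr(state, "world")
  df <- data.frame(
    id = seq_along(a$alive),
    alive = a$alive == 1L,
    x = a$col, y = world$height - (a$row + 1L),
    type = c("emotional", "rational")[a$type + 1L],
    state = .STATE_LEVELS[a$state + 1L],
    current_exit = .EXIT_LEVELS[a$exit],
    moving_index = a$moving_index, waiting_index = a$waiting_index,
    panic_index = a$panic_index, mobility_index = a$mobility_index,
    heading = ifelse(a$heading < 0, NA_integer_, a$heading),
    distant_contact = ifelse(a$distant == 0L, NA_integer_, a$distant),
    ever_panicked = a$ever_panicked == 1L,
    stringsAsFactors = FALSE)
  if (alive_only) df <- df[df$alive, , drop = FALSE]
  df
}

#' Run a complete evacuation simulation
#'
#' Iterates the engine until the world is empty or `max_ticks` is reached.
#' The run is fully determined by the configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @param record_log Keep a per-tick log (population, cumulative exits,
#'   concurrently panicking agents).
#' @param record_trace Keep a per-agent per-tick trace (tick, id, x, y,
#'   state, exit, Mobility Index); memory-hungry, intended for small runs.
#' @param keep_state Attach the final `sim_state` to the result.
#' @return A `run_result`: exit time (ticks until empty), per-exit usage
#'   counts, the maximum number of concurrently panicking agents, the
#'   number of rational and emotional agents that ever entered PANIC, and a
#'   `terminated` flag (`FALSE` when `max_ticks` was hit with agents
#'   remaining, e.g. on maps with sealed pockets).
#' @export
run_simulation <- function(config, record_log = TRUE, record_trace = FALSE,
                           keep_state = FALSE) {
  state <- sim_init(config)
  world <- attr(state, "world")
  out <- cpp_run(unclass(state), engine_config(config, world),
                 record_log, record_trace)
  res <- list(
    exit_time = out$exit_time,
    exited = c(left = out$exited_left, right = out$exited_right),
    max_concurrent_panic = out$max_concurrent_panic,
    ever_panicked = c(rational = out$ever_panicked_rational,
                      emotional = out$ever_panicked_emotional),
    terminated = out$terminated,
    n_agents = config$n_agents,
    strategy = config$strategy,
    seed = config$seed,
    config = config)
  if (record_log) res$log <- out$log
  if (record_trace) {
    tr <- out$trace
    tr$x <- tr$col
    tr$y <- world$height - (tr$row + 1L)
    tr$state <- ifelse(tr$state < 0, "EXITED", .STATE_LEVELS[tr$state + 1L])
    tr$exit <- .EXIT_LEVELS[tr$exit]
    res$trace <- tr[, c("tick", "id", "x", "y", "state", "exit",
                        "mobility_index")]
  }
  if (keep_state) {
    st <- out$state
    attr(st, "world") <- world
    res$final_state <- st
  }
  class(res) <- "run_result"
  res
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> strategy %s, %d agents, seed %d\n",
              x$strategy, x$n_agents, x$seed))
  cat(sprintf("  exit time: %d ticks%s\n", x$exit_time,
              if (x$terminated) "" else " (NOT terminated: max_ticks reached)"))
  cat(sprintf("  exit usage: left %d, right %d\n",
              x$exited["left"], x$exited["right"]))
  cat(sprintf("  panic: max concurrent %d; ever panicked: %d rational, %d emotional\n",
              x$max_concurrent_panic, x$ever_panicked["rational"],
              x$ever_panicked["emotional"]))
  invisible(x)
}
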