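test_that("agents are placed uniquely with the requested type mix", {
  w <- build_preset("E1", 21)
  set.seed(5)
  a <- initialize_agents(w, 100, rational_pct = 5)
  expect_equal(nrow(a), 100)
  expect_equal(sum(a$type == "rational"), 5)
  expect_equal(anyDuplicated(paste(a$x, a$y)), 0)
  expect_true(all(a$state == "WALK"))
  expect_true(all(a$moving_index == 0 & a$waiting_index == 0 &
                    a$panic_index == 0 & a$mobility_index == 0))
  expect_false(any(a$ever_panicked))
  # all on normal patches, never on exits or obstacles
  types <- vapply(seq_len(nrow(a)),
                  function(i) patch_info(w, a$x[i], a$y[i])$structure_type,
                  character(1))
  expect_true(all(types == "normal"))
  # current exit is the nearer exit by hop count
  for (i in sample(nrow(a), 20)) {
    p <- patch_info(w, a$x[i], a$y[i])
    if (p$hops[["left"]] != p$hops[["right"]])
      expect_equal(a$current_exit[i],
                   if (p$hops[["left"]] < p$hops[["right"]]) "left" else "right")
  }
})

test_that("placement is seed-deterministic and capacity-checked", {
  w <- build_preset("E1", 11)
  set.seed(9); a <- initialize_agents(w, 10, 50)
  set.seed(9); b <- initialize_agents(w, 10, 50)
  expect_identical(a, b)
  expect_error(initialize_agents(w, 10000, 0), "config error")
  set.seed(1)
  expect_equal(nrow(initialize_agents(w, 0, 0)), 0)
})

test_that("heading adjustment reads the floor field of the current exit", {
  w <- compute_floor_field(load_map(c(".....", ".....", ".....", "L...R")))
  agent <- list(x = 2, y = 2, current_exit = "left", heading = NA_integer_)
  expect_equal(adjust_heading(agent, w)$heading,
               patch_info(w, 2, 2)$doms[["left"]])
  agent$current_exit <- "right"
  expect_equal(adjust_heading(agent, w)$heading,
               patch_info(w, 2, 2)$doms[["right"]])
  # unreachable pocket: heading is kept
  wp <- compute_floor_field(load_map(generate_fixture_world("pocket", 9)))
  df <- as.data.frame(wp)
  hole <- df[df$structure_type == "normal" & df$hops_left == -1, ][1, ]
  agent <- list(x = hole$x, y = hole$y, current_exit = "left", heading = 45L)
  expect_equal(adjust_heading(agent, wp)$heading, 45L)
})

test_that("next-cell selection follows the dial order around the heading", {
  w <- compute_floor_field(load_map(c("L....", ".....", ".....", ".....",
                                      "....R")))
  a <- list(id = 1L, x = 2, y = 2, heading = 90L)
  occ <- matrix(0L, 5, 5)
  out <- select_next_cell(a, w, occ)
  expect_true(out$moved)
  expect_equal(unname(out$new_pos), c(3, 2))    # due east
  expect_equal(out$chosen_offset_rank, 1)
  # ahead occupied: rank 2 is +45 degrees clockwise (southeast of east)
  occ[5 - 2, 3 + 1] <- 9L
  out2 <- select_next_cell(a, w, occ)
  expect_equal(out2$chosen_offset_rank, 2)
  expect_equal(unname(out2$new_pos), c(3, 1))
  # fully surrounded: no move
  occ2 <- matrix(9L, 5, 5)
  occ2[5 - 2, 2 + 1] <- 0L
  out3 <- select_next_cell(a, w, occ2)
  expect_false(out3$moved)
  expect_null(out3$new_pos)
})

test_that("contended cells are claimed atomically in activation order", {
  # 1 x 5 strip, both agents can only move to the shared center cell
  S <- matrix(c(1L, 0L, 0L, 0L, 1L), 1, 5)
  for (first in 1:2) {
    occ <- matrix(0L, 1, 5)
    occ[1, 2] <- 1L; occ[1, 4] <- 2L
    heads <- c(90L, 270L)   # agent 1 faces east, agent 2 west
    cols <- c(1L, 3L)
    moved <- logical(2)
    for (a in if (first == 1) 1:2 else 2:1) {
      res <- evacsim:::cpp_select_next_cell(S, occ, 0L, cols[a], heads[a])
      moved[a] <- res$moved
      if (res$moved) {
        occ[1, cols[a] + 1] <- 0L
        occ[res$row + 1, res$col + 1] <- a
      }
    }
    expect_equal(sum(moved), 1)     # exactly one wins the cell
    expect_true(moved[first])
  }
})

test_that("the move outcome drives the WALK/WAIT/PANIC indices exclusively", {
  a <- list(x = 1, y = 1, state = "WALK", moving_index = 0L,
            waiting_index = 0L, panic_index = 0L, ever_panicked = FALSE)
  ok <- list(moved = TRUE, new_pos = c(x = 2, y = 1), chosen_offset_rank = 1)
  blocked <- list(moved = FALSE, new_pos = NULL, chosen_offset_rank = NULL)
  for (i in 1:3) a <- apply_move_and_update_state(a, ok, 4)
  expect_equal(a$state, "WALK")
  expect_equal(c(a$moving_index, a$waiting_index, a$panic_index), c(3, 0, 0))
  # blocked below threshold: WAIT
  a <- apply_move_and_update_state(a, blocked, 4)
  expect_equal(a$state, "WAIT")
  expect_equal(c(a$moving_index, a$waiting_index, a$panic_index), c(0, 1, 0))
  # waiting index at the threshold: PANIC with panic index 1
  a$waiting_index <- 4L
  a <- apply_move_and_update_state(a, blocked, 4)
  expect_equal(a$state, "PANIC")
  expect_equal(c(a$moving_index, a$waiting_index, a$panic_index), c(0, 0, 1))
  expect_true(a$ever_panicked)
  # panicking agent that moves returns to WALK, panic index reset
  a <- apply_move_and_update_state(a, ok, 4)
  expect_equal(a$state, "WALK")
  expect_equal(c(a$moving_index, a$waiting_index, a$panic_index), c(1, 0, 0))
  expect_true(a$ever_panicked)   # latched
})

test_that("mobility index follows +1/-1/contraction and stays unclamped", {
  mi <- function(m, s) update_mobility_index(
    list(mobility_index = m, state = s))$mobility_index
  expect_equal(mi(8, "PANIC"), 4)      # halved at sensitivity 0.5
  expect_equal(mi(0, "PANIC"), 0)      # fixed point
  expect_equal(mi(0, "WAIT"), -1)      # no clamping
  expect_equal(mi(-1, "PANIC"), -0.5)  # magnitude halves for negatives too
  expect_equal(mi(2.5, "WALK"), 3.5)
  expect_equal(mi(6, "PANIC"), 6 - 6 * 0.5)
  a <- update_mobility_index(list(mobility_index = 10, state = "PANIC"),
                             sensitivity = 0.25)
  expect_equal(a$mobility_index, 7.5)
})

test_that("a lone agent crosses an open room in Chebyshev-distance ticks", {
  rows <- generate_fixture_world("open", 11)
  for (seed in 1:5) {
    cfg <- sim_config(rows, n_agents = 1, seed = seed)
    st <- sim_init(cfg)
    ag <- state_agents(st)
    d <- patch_info(attr(st, "world"), ag$x, ag$y)$hops[[ag$current_exit]]
    r <- run_simulation(cfg)
    expect_equal(r$exit_time, d)
    expect_equal(sum(r$exited), 1)
  }
})

test_that("index exclusivity and occupancy safety hold every tick", {
  cfg <- sim_config(generate_fixture_world("asymmetric", 15), n_agents = 80,
                    rational_pct = 20, strategy = "S2", seed = 13)
  st <- sim_init(cfg)
  for (t in 1:25) {
    st <- sim_step(st, cfg)
    ag <- state_agents(st, alive_only = TRUE)
    nonzero <- (ag$moving_index > 0) + (ag$waiting_index > 0) +
      (ag$panic_index > 0)
    expect_true(all(nonzero <= 1))
    expect_equal(anyDuplicated(paste(ag$x, ag$y)), 0)
    # panic state and panic index agree right after the update
    expect_equal(ag$state == "PANIC", ag$panic_index >= 1)
    # occupancy matrix mirrors agent positions
    occ <- st$occupancy
    expect_equal(sort(occ[occ > 0]), sort(ag$id))
  }
})
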