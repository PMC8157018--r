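# Branch probabilities are checked by Monte-Carlo at n draws against
# binomial 3-standard-error bands.
expect_freq <- function(observed, p, n) {
  se <- sqrt(max(p * (1 - p), 1e-12) / n)
  expect_lt(abs(observed - p), max(3 * se, 1e-9))
}

switch_freq <- function(n, ...) {
  mean(decide_exit(..., current_exit = "left", n = n) == "right")
}

test_that("neighbor sampling is uniform over the Moore occupants", {
  w <- compute_floor_field(load_map(c("L....", ".....", ".....", ".....",
                                      "....R")))
  agents <- data.frame(id = 1:4, x = c(2, 1, 2, 3), y = c(2, 2, 3, 1))
  focal <- agents[1, ]
  set.seed(21)
  draws <- replicate(30000, pick_random_neighbor(focal, w, agents))
  tab <- table(draws)
  expect_setequal(names(tab), c("2", "3", "4"))
  expect_true(all(abs(tab / 30000 - 1 / 3) < 0.01))
  # empty neighborhood
  lone <- data.frame(id = 1L, x = 2, y = 2)
  expect_true(is.na(pick_random_neighbor(lone[1, ], w, lone)))
})

test_that("distant ties are one per rational agent, uniform and static", {
  a <- data.frame(id = 1:10, type = c(rep("rational", 2), rep("emotional", 8)),
                  distant_contact = NA_integer_)
  set.seed(3)
  linked <- establish_distant_links(a)
  expect_equal(sum(!is.na(linked$distant_contact)), 2)
  expect_true(all(is.na(linked$distant_contact[linked$type == "emotional"])))
  expect_true(all(linked$distant_contact[1:2] != 1:2, na.rm = TRUE))
  set.seed(3)
  expect_identical(establish_distant_links(a), linked)
  # a single agent has nobody to link to
  solo <- data.frame(id = 1L, type = "rational", distant_contact = NA_integer_)
  expect_true(is.na(establish_distant_links(solo)$distant_contact))
  # uniformity across the 99 possible endpoints
  b <- data.frame(id = 1:100, type = c("rational", rep("emotional", 99)),
                  distant_contact = NA_integer_)
  set.seed(17)
  draws <- replicate(20000, establish_distant_links(b)$distant_contact[1])
  expect_gt(chisq.test(table(factor(draws, levels = 2:100)))$p.value, 0.001)
})

test_that("the max-mobility contact is the MI argmax with random tie-break", {
  w <- compute_floor_field(load_map(c("L....", ".....", ".....", ".....",
                                      "....R")))
  agents <- data.frame(id = 1:4, x = c(2, 1, 2, 0), y = c(2, 2, 3, 0),
                       mobility_index = c(0, 2, 5, 3),
                       distant_contact = c(4L, NA, NA, NA))
  expect_equal(pick_max_mobility_contact(agents[1, ], w, agents), 3L)
  # only the distant contact, even with negative MI
  far <- data.frame(id = 1:2, x = c(2, 0), y = c(2, 0),
                    mobility_index = c(0, -1), distant_contact = c(2L, NA))
  expect_equal(pick_max_mobility_contact(far[1, ], w, far), 2L)
  # exited endpoint makes the tie inert
  gone <- far[1, ]
  expect_true(is.na(pick_max_mobility_contact(gone, w, gone)))
  # tie between two candidates resolves 50/50
  tie <- data.frame(id = 1:3, x = c(2, 1, 3), y = c(2, 2, 2),
                    mobility_index = c(0, 4, 4), distant_contact = NA_integer_)
  set.seed(31)
  picks <- replicate(10000, pick_max_mobility_contact(tie[1, ], w, tie))
  expect_freq(mean(picks == 2L), 0.5, 10000)
})

test_that("S1 never switches and decisions stay within the two exits", {
  expect_true(all(decide_exit("S1", "rational", 5, "left",
                              neighbor_exit = "right", n = 200) == "left"))
  set.seed(2)
  out <- decide_exit("S2", "rational", 0, "right", neighbor_exit = "left",
                     n = 500)
  expect_true(all(out %in% c("left", "right")))
})

test_that("S2 branches reproduce the published switch probabilities", {
  n <- 1e5
  set.seed(41)
  # rational, calm
  expect_freq(switch_freq(n, "S2", "rational", 0, neighbor_exit = "left"),
              0.10, n)
  expect_freq(switch_freq(n, "S2", "rational", 0, neighbor_exit = "right"),
              0.90, n)
  # rational, panicking: certain switch on agreement, keep on disagreement
  expect_equal(switch_freq(1000, "S2", "rational", 2, neighbor_exit = "left"), 1)
  expect_equal(switch_freq(1000, "S2", "rational", 2, neighbor_exit = "right"), 0)
  # emotional: only a panicking agent deviates, adopting the neighbor's exit
  expect_freq(switch_freq(n, "S2", "emotional", 1, neighbor_exit = "right"),
              0.10, n)
  expect_equal(switch_freq(1000, "S2", "emotional", 0, neighbor_exit = "right"), 0)
  expect_equal(switch_freq(1000, "S2", "emotional", 1, neighbor_exit = "left"), 0)
  # no neighbor: keep
  expect_equal(switch_freq(1000, "S2", "rational", 0), 0)
})

test_that("S3 follows its decision table and is inert for emotional agents", {
  n <- 4e4
  tab <- decision_probs()$s3_table
  ctx <- expand.grid(panic = c(0, 1), ne = c("left", "right"),
                     ep = c("left", "right"), stringsAsFactors = FALSE)
  set.seed(43)
  for (i in seq_len(nrow(ctx))) {
    idx <- ctx$panic[i] * 4 + (ctx$ne[i] != "left") * 2 +
      (ctx$ep[i] != "left") + 1
    expect_freq(switch_freq(n, "S3", "rational", ctx$panic[i],
                            neighbor_exit = ctx$ne[i],
                            dominant_exit = ctx$ep[i]),
                tab[idx], n)
  }
  # emotional agents under S3 never switch
  expect_equal(switch_freq(1000, "S3", "emotional", 1,
                           neighbor_exit = "right", dominant_exit = "right"), 0)
  # missing neighbor or missing dominant potential: keep
  expect_equal(switch_freq(1000, "S3", "rational", 1,
                           dominant_exit = "right"), 0)
  expect_equal(switch_freq(1000, "S3", "rational", 1,
                           neighbor_exit = "right"), 0)
})

test_that("S4 matches S2 except panicking rationals adopt the contact's exit", {
  n <- 1e5
  set.seed(47)
  expect_freq(switch_freq(n, "S4", "rational", 0, neighbor_exit = "left"),
              0.10, n)
  expect_freq(switch_freq(n, "S4", "rational", 0, neighbor_exit = "right"),
              0.90, n)
  expect_freq(switch_freq(n, "S4", "emotional", 1, neighbor_exit = "right"),
              0.10, n)
  # panicking rational: contact's exit verbatim, keep when no contact
  expect_equal(switch_freq(500, "S4", "rational", 3, neighbor_exit = "left",
                           contact_exit = "right"), 1)
  expect_equal(switch_freq(500, "S4", "rational", 3, neighbor_exit = "left",
                           contact_exit = "left"), 0)
  expect_equal(switch_freq(500, "S4", "rational", 3), 0)
})
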