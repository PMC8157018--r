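# Shared fixtures: all test worlds are generated in code.

# random rectangular map with obstacles and one exit patch per label
random_map <- function(height, width, obstacle_p = 0.2) {
  m <- matrix(ifelse(runif(height * width) < obstacle_p, "#", "."),
              height, width)
  free <- sample(length(m), 2L)
  m[free[1]] <- "L"
  m[free[2]] <- "R"
  apply(m, 1L, paste0, collapse = "")
}

# independent shortest-path oracle: hop counts on the 8-connected
# walkability graph via igraph, -1 sentinel for obstacle/exit/unreachable
oracle_hops <- function(world, exit_label) {
  h <- world$height
  w <- world$width
  walk <- world$structure != 1L
  idx <- matrix(seq_len(h * w), h, w)
  edges <- NULL
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))) {
    dr <- off[1]; dc <- off[2]
    rr <- max(1, 1 - dr):min(h, h - dr)
    cc <- max(1, 1 - dc):min(w, w - dc)
    a <- idx[rr, cc, drop = FALSE]
    b <- idx[rr + dr, cc + dc, drop = FALSE]
    keep <- walk[a] & walk[b]
    edges <- rbind(edges, cbind(a[keep], b[keep]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, h * w - igraph::vcount(g)))
  code <- if (exit_label == "left") 2L else 3L
  src <- which(world$structure == code)
  d <- suppressWarnings(igraph::distances(g, v = src, to = seq_len(h * w)))
  dmin <- apply(d, 2, min)
  out <- matrix(-1, h, w)
  reach <- world$structure == 0L & is.finite(dmin)
  out[reach] <- dmin[reach]
  out
}

# greedy descent along doms; terminates on any exit patch (an agent is
# absorbed by whichever exit it steps onto). Returns the steps taken and
# the label of the exit reached, or NA fields on failure.
follow_doms <- function(world, x, y, exit_label) {
  offs <- list(`0` = c(0, 1), `45` = c(1, 1), `90` = c(1, 0),
               `135` = c(1, -1), `180` = c(0, -1), `225` = c(-1, -1),
               `270` = c(-1, 0), `315` = c(-1, 1))  # (dx, dy)
  steps <- 0L
  repeat {
    p <- patch_info(world, x, y)
    if (p$structure_type == "exit")
      return(list(steps = steps, reached = p$exit_label))
    if (p$structure_type == "obstacle")
      return(list(steps = NA_integer_, reached = NA_character_))
    dom <- p$doms[[exit_label]]
    if (dom < 0) return(list(steps = NA_integer_, reached = NA_character_))
    d <- offs[[as.character(dom)]]
    x <- x + d[1]; y <- y + d[2]
    steps <- steps + 1L
    if (steps > world$width * world$height)
      return(list(steps = NA_integer_, reached = NA_character_))
  }
}

# effective hop value treating exit patches as distance 0 and
# obstacle/unreachable as Inf, for neighbor-consistency checks
effective_hops <- function(world, exit_label) {
  code <- if (exit_label == "left") 2L else 3L
  eh <- matrix(Inf, world$height, world$width)
  hl <- world$hops[[exit_label]]
  eh[hl >= 0] <- hl[hl >= 0]
  eh[world$structure == code] <- 0
  eh
}
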