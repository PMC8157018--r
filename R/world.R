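# Grid environment: map parsing, preset geometries, Moore neighborhoods and
# the floor field (per-exit hop counts and best directions).
#
# Coordinates exposed to users are 0-based with x = column and y = row,
# origin at the bottom-left corner; map files list the TOP row first.
# Internally patches live in height x width matrices indexed [row, col]
# with row 1 at the top, so y = height - row (1-based row).

MAP_ALPHABET <- c("." = 0L, "#" = 1L, "L" = 2L, "R" = 3L)

rc_from_xy <- function(world, x, y) {
  cbind(row = world$height - y, col = x + 1L)
}

xy_from_rc <- function(world, row, col) {
  cbind(x = col - 1L, y = world$height - row)
}

#' Parse a plain-text map into a grid world
#'
#' Map files are rectangular character grids over the alphabet `.` (floor),
#' `#` (obstacle), `L` (left-exit patch) and `R` (right-exit patch); the
#' first line is the top row of the world. The returned world has its floor
#' field uninitialized (hop counts and directions hold the `-1` sentinel,
#' potentials are 0); call [compute_floor_field()] before simulating.
#'
#' @param map_text Character vector of rows, or a single string containing
#'   newlines.
#' @return A `grid_world` object.
#' @seealso [read_map()], [build_preset()], [compute_floor_field()]
#' @examples
#' w <- load_map(c("L..", "...", "..R"))
#' w$width
#' @export
load_map <- function(map_text) {
  if (length(map_text) == 1L && grepl("\n", map_text, fixed = TRUE))
    map_text <- strsplit(map_text, "\n", fixed = TRUE)[[1]]
  map_text <- map_text[nchar(map_text) > 0L | seq_along(map_text) < length(map_text)]
  if (length(map_text) == 0L)
    stop("map is empty", call. = FALSE)
  widths <- nchar(map_text)
  if (length(unique(widths)) != 1L)
    stop("map format error: ragged rows (widths ",
         paste(unique(widths), collapse = ", "), ")", call. = FALSE)
  h <- length(map_text)
  w <- widths[1]
  chars <- matrix(unlist(strsplit(map_text, "", fixed = TRUE), use.names = FALSE),
                  nrow = h, ncol = w, byrow = TRUE)
  bad <- setdiff(unique(as.vector(chars)), names(MAP_ALPHABET))
  if (length(bad) > 0L)
    stop("map format error: unknown character(s) ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  S <- matrix(MAP_ALPHABET[chars], nrow = h, ncol = w)
  if (!any(S == 2L)) stop("missing-exit error: no left exit ('L') in map", call. = FALSE)
  if (!any(S == 3L)) stop("missing-exit error: no right exit ('R') in map", call. = FALSE)

  world <- list(
    width = w, height = h,
    structure = S,
    exits = lapply(c(left = 2L, right = 3L), function(code) {
      idx <- which(S == code, arr.ind = TRUE)
      data.frame(x = unname(idx[, "col"]) - 1L, y = h - unname(idx[, "row"]),
                 row.names = NULL)
    }),
    hops = list(left = matrix(-1L, h, w), right = matrix(-1L, h, w)),
    doms = list(left = matrix(-1L, h, w), right = matrix(-1L, h, w)),
    pv   = list(left = matrix(0, h, w), right = matrix(0, h, w)),
    has_field = FALSE)
  class(world) <- "grid_world"
  world
}

#' @rdname load_map
#' @param path Path to a map file.
#' @export
read_map <- function(path) load_map(readLines(path))

#' Serialize a grid world back to map text
#'
#' @param world A `grid_world`.
#' @param path Optional file path; when `NULL` the character vector of rows
#'   is returned invisibly-visibly.
#' @return Character vector of map rows (invisibly when written to a file).
#' @export
map_text <- function(world, path = NULL) {
  chars <- names(MAP_ALPHABET)[world$structure + 1L]
  m <- matrix(chars, world$height, world$width)
  rows <- apply(m, 1L, paste0, collapse = "")
  if (!is.null(path)) {
    writeLines(rows, path)
    return(invisible(rows))
  }
  rows
}

#' Moore neighborhood of a patch
#'
#' Returns the in-bounds cells of the 3x3 block around `(x, y)` (the center
#' excluded), in the fixed scan order N, NE, E, SE, S, SW, W, NW. Directions
#' are compass degrees with 0 = north (up, towards larger y), clockwise.
#'
#' @param world A `grid_world`.
#' @param x,y Patch coordinates (0-based, origin bottom-left).
#' @return A data frame with columns `direction`, `x`, `y`.
#' @export
moore_neighbors <- function(world, x, y) {
  stopifnot(x >= 0, x < world$width, y >= 0, y < world$height)
  rc <- rc_from_xy(world, x, y)
  rr <- rc[1, "row"] + .SCAN_OFFSETS[, 1]
  cc <- rc[1, "col"] + .SCAN_OFFSETS[, 2]
  ok <- rr >= 1L & rr <= world$height & cc >= 1L & cc <= world$width
  data.frame(direction = .SCAN_ANGLES[ok],
             x = cc[ok] - 1L, y = world$height - rr[ok])
}

# out[r, c] = M[r + dr, c + dc], `fill` outside the lattice
shift_mat <- function(M, dr, dc, fill) {
  h <- nrow(M); w <- ncol(M)
  out <- matrix(fill, h, w)
  rr <- max(1L, 1L - dr):min(h, h - dr)
  cc <- max(1L, 1L - dc):min(w, w - dc)
  if (length(rr) > 0L && length(cc) > 0L && rr[1] <= rr[length(rr)] &&
      cc[1] <= cc[length(cc)])
    out[rr, cc] <- M[rr + dr, cc + dc]
  out
}

#' Compute the floor field (hop counts and directions) for both exits
#'
#' For each exit label independently, every walkable patch reachable from
#' that exit through Moore adjacency (never passing through an obstacle)
#' receives in `hops` the minimal number of cell-to-cell steps to any patch
#' of that exit, and in `doms` the compass direction towards the neighbor
#' through which that minimum is achieved. The spread starts at the exit
#' patches (distance 0); exit and obstacle patches themselves keep the `-1`
#' sentinel in both fields, and so do unreachable patches. When two
#' neighbors report the same minimal hop count, the direction is taken from
#' the first in the scan order N, NE, E, SE, S, SW, W, NW.
#'
#' @param world A `grid_world`.
#' @return The world with `hops` and `doms` filled and `has_field = TRUE`.
#' @export
compute_floor_field <- function(world) {
  h <- world$height; w <- world$width
  walk <- world$structure != 1L
  for (lab in .EXIT_LEVELS) {
    code <- .STRUCT_CODES[[if (lab == "left") "exit_left" else "exit_right"]]
    dist <- matrix(Inf, h, w)
    frontier <- which(world$structure == code)
    dist[frontier] <- 0
    d <- 0
    while (length(frontier) > 0L) {
      fr <- ((frontier - 1L) %% h) + 1L
      fc <- ((frontier - 1L) %/% h) + 1L
      nxt <- integer(0)
      for (k in 1:8) {
        rr <- fr + .SCAN_OFFSETS[k, 1]
        cc <- fc + .SCAN_OFFSETS[k, 2]
        ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
        idx <- (cc[ok] - 1L) * h + rr[ok]
        nxt <- c(nxt, idx[walk[idx] & is.infinite(dist[idx])])
      }
      nxt <- unique(nxt)
      d <- d + 1
      dist[nxt] <- d
      frontier <- nxt
    }
    normal <- world$structure == 0L
    reached <- normal & is.finite(dist)
    hops <- matrix(-1L, h, w)
    hops[reached] <- as.integer(dist[reached])
    doms <- matrix(-1L, h, w)
    for (k in 1:8) {
      nd <- shift_mat(dist, .SCAN_OFFSETS[k, 1], .SCAN_OFFSETS[k, 2], Inf)
      hit <- reached & doms == -1L & nd == dist - 1
      doms[hit] <- .SCAN_ANGLES[k]
    }
    world$hops[[lab]] <- hops
    world$doms[[lab]] <- doms
  }
  world$has_field <- TRUE
  world
}

#' Preset two-exit environments of increasing asymmetry
#'
#' Builds the square preset rooms E1--E4: a bounded `size` x `size` lattice
#' with a three-patch left exit centered on the west wall and a three-patch
#' right exit centered on the east wall. E1 is an open room; E2--E4 add a
#' vertical obstacle wall three columns in front of the right exit whose
#' length grows with the preset, so the fraction of walkable patches nearer
#' the left exit (by hop count) increases strictly from E1 to E4. The floor
#' field is computed before the world is returned.
#'
#' @param preset One of `"E1"`, `"E2"`, `"E3"`, `"E4"`.
#' @param size Odd side length, at least 11 (default 51 gives the standard
#'   2,601-cell world).
#' @return A `grid_world` with the floor field computed.
#' @export
build_preset <- function(preset = c("E1", "E2", "E3", "E4"), size = 51L) {
  preset <- match.arg(preset)
  size <- as.integer(size)
  if (size < 11L || size %% 2L == 0L)
    stop("config error: preset size must be odd and at least 11", call. = FALSE)
  rows <- matrix(".", size, size)
  mid <- (size + 1L) %/% 2L
  rows[(mid - 1L):(mid + 1L), 1L] <- "L"
  rows[(mid - 1L):(mid + 1L), size] <- "R"
  wall_frac <- c(E1 = 0, E2 = 0.30, E3 = 0.55, E4 = 0.80)
  f <- wall_frac[[preset]]
  if (f > 0) {
    len <- round(f * (size - 2L))
    if (len %% 2L == 0L) len <- len + 1L
    len <- min(len, size - 4L)
    half <- (len - 1L) %/% 2L
    rows[(mid - half):(mid + half), size - 3L] <- "#"
  }
  world <- load_map(apply(rows, 1L, paste0, collapse = ""))
  compute_floor_field(world)
}

#' Environment specification
#'
#' Bundles either a preset id or a custom map text, plus the side length for
#' presets, so run and sweep configurations can carry environments by value.
#'
#' @param preset_id One of `"E1"`--`"E4"` or `"custom"`.
#' @param map_text Required iff `preset_id = "custom"`: map rows as accepted
#'   by [load_map()].
#' @param size Side length for presets (ignored for custom maps).
#' @return An `environment_spec` object.
#' @export
environment_spec <- function(preset_id = c("E1", "E2", "E3", "E4", "custom"),
                             map_text = NULL, size = 51L) {
  preset_id <- match.arg(preset_id)
  if (preset_id == "custom" && is.null(map_text))
    stop("config error: custom environment requires map_text", call. = FALSE)
  if (preset_id != "custom" && !is.null(map_text))
    stop("config error: map_text is only allowed with preset_id = 'custom'",
         call. = FALSE)
  structure(list(preset_id = preset_id, map_text = map_text,
                 size = as.integer(size)),
            class = "environment_spec")
}

#' Realize an environment specification as a grid world
#'
#' @param env An `environment_spec`, a preset id string, a character vector
#'   of map rows, or an existing `grid_world`.
#' @param size Preset side length used when `env` is a preset id.
#' @return A `grid_world` with the floor field computed.
#' @export
build_world <- function(env, size = 51L) {
  if (inherits(env, "grid_world")) {
    if (!env$has_field) env <- compute_floor_field(env)
    return(env)
  }
  if (inherits(env, "environment_spec")) {
    if (env$preset_id != "custom")
      return(build_preset(env$preset_id, env$size))
    return(compute_floor_field(load_map(env$map_text)))
  }
  if (is.character(env)) {
    if (length(env) == 1L && env %in% c("E1", "E2", "E3", "E4"))
      return(build_preset(env, size))
    return(compute_floor_field(load_map(env)))
  }
  stop("config error: cannot interpret 'env' as an environment", call. = FALSE)
}

#' Per-patch view of a grid world
#'
#' @param world A `grid_world`.
#' @param x,y Patch coordinates (0-based).
#' @return A list with the patch's structure type, exit label, per-exit hop
#'   counts, directions and potential values.
#' @export
patch_info <- function(world, x, y) {
  rc <- rc_from_xy(world, x, y)
  r <- rc[1, "row"]; c <- rc[1, "col"]
  code <- world$structure[r, c]
  list(
    x = x, y = y,
    structure_type = c("normal", "obstacle", "exit", "exit")[code + 1L],
    exit_label = c("none", "none", "left", "right")[code + 1L],
    hops = c(left = world$hops$left[r, c], right = world$hops$right[r, c]),
    doms = c(left = world$doms$left[r, c], right = world$doms$right[r, c]),
    pv   = c(left = world$pv$left[r, c],  right = world$pv$right[r, c]))
}

#' @export
as.data.frame.grid_world <- function(x, ...) {
  h <- x$height; w <- x$width
  rows <- rep(seq_len(h), times = w)
  cols <- rep(seq_len(w), each = h)
  code <- as.vector(x$structure)
  data.frame(
    x = cols - 1L, y = h - rows,
    structure_type = c("normal", "obstacle", "exit", "exit")[code + 1L],
    exit_label = c("none", "none", "left", "right")[code + 1L],
    hops_left = as.vector(x$hops$left), hops_right = as.vector(x$hops$right),
    doms_left = as.vector(x$doms$left), doms_right = as.vector(x$doms$right),
    pv_left = as.vector(x$pv$left), pv_right = as.vector(x$pv$right))
}

#' @export
print.grid_world <- function(x, ...) {
  n_ob <- sum(x$structure == 1L)
  cat(sprintf("<grid_world> %d x %d (%d patches)\n", x$width, x$height,
              x$width * x$height))
  cat(sprintf("  exits: left %d patch(es), right %d patch(es); obstacles: %d\n",
              nrow(x$exits$left), nrow(x$exits$right), n_ob))
  cat(sprintf("  floor field: %s\n",
              if (x$has_field) "computed" else "not computed"))
  invisible(x)
}

# fraction of walkable (normal) patches strictly nearer the left exit;
# used to rank environment asymmetry
fraction_nearer_left <- function(world) {
  stopifnot(world$has_field)
  normal <- world$structure == 0L
  hl <- world$hops$left[normal]
  hr <- world$hops$right[normal]
  hl[hl < 0] <- Inf
  hr[hr < 0] <- Inf
  mean(hl < hr)
}
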