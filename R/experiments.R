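# Batch experiment sweeps over environments x strategies x rational
# fractions, replicate seeding for paired comparisons, CSV output, and
# synthetic fixture environments for testing.

#' Specify an experiment sweep
#'
#' Describes the full factorial design environment x strategy x
#' rational-percentage, each cell repeated `replicates` times. Replicate
#' `i` always runs with seed `base_seed + i - 1`, so the same replicate
#' index reuses identical initial placements across strategies and
#' percentages — comparisons across cells are paired by seed.
#'
#' @param envs Environments: character vector of preset ids, or a (named)
#'   list of anything [build_world()] accepts.
#' @param strategies Character vector among `"S1"`--`"S4"`.
#' @param rational_pcts Numeric vector of rational percentages.
#' @param replicates Repeats per cell (the standard design uses 50).
#' @param base_seed Seed of replicate 1.
#' @param n_agents Evacuees per run.
#' @param size Preset side length.
#' @param ... Further arguments passed to [sim_config()] (thresholds,
#'   decay, probabilities, ...).
#' @return A `sweep_spec` object.
#' @export
sweep_spec <- function(envs = c("E1", "E2", "E3", "E4"),
                       strategies = c("S1", "S2", "S3", "S4"),
                       rational_pcts = c(5, 10, 15, 20),
                       replicates = 50L, base_seed = 1L,
                       n_agents = 1000L, size = 51L, ...) {
  stopifnot(replicates >= 1L)
  strategies <- match.arg(strategies, .STRATEGIES, several.ok = TRUE)
  if (is.character(envs)) {
    envs <- as.list(envs)
    names(envs) <- unlist(envs)
  }
  if (is.null(names(envs)) || any(names(envs) == ""))
    names(envs) <- paste0("env", seq_along(envs))
  structure(list(envs = envs, strategies = strategies,
                 rational_pcts = rational_pcts,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 n_agents = as.integer(n_agents), size = as.integer(size),
                 config_args = list(...)),
            class = "sweep_spec")
}

#' Run an experiment sweep
#'
#' Executes every (environment, strategy, rational percentage, replicate)
#' combination with derived seeds and collects one row per run plus a
#' per-cell mean/sd summary. Runs that hit `max_ticks` with agents still in
#' the world are flagged `terminated = FALSE`, excluded from the summary
#' means, and reported with a warning.
#'
#' @param spec A [sweep_spec()].
#' @param verbose Print one line per completed cell.
#' @return A `sweep_result`: list with `rows` (one data-frame row per run)
#'   and `summary` (per-cell means and standard deviations over terminated
#'   runs).
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- list()
  for (env_name in names(spec$envs)) {
    # realize once; worlds are immutable across runs
    world <- build_world(spec$envs[[env_name]], size = spec$size)
    for (strategy in spec$strategies) {
      for (pct in spec$rational_pcts) {
        for (rep_i in seq_len(spec$replicates)) {
          cfg_args <- c(list(env = world, n_agents = spec$n_agents,
                             rational_pct = pct, strategy = strategy,
                             seed = spec$base_seed + rep_i - 1L),
                        spec$config_args)
          res <- run_simulation(do.call(sim_config, cfg_args),
                                record_log = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            env = env_name, strategy = strategy, rational_pct = pct,
            replicate = rep_i, seed = res$seed,
            exit_time = res$exit_time,
            exited_left = unname(res$exited["left"]),
            exited_right = unname(res$exited["right"]),
            max_concurrent_panic = res$max_concurrent_panic,
            ever_panicked_rational = unname(res$ever_panicked["rational"]),
            ever_panicked_emotional = unname(res$ever_panicked["emotional"]),
            terminated = res$terminated,
            stringsAsFactors = FALSE)
        }
        if (verbose)
          message(sprintf("done: %s %s %g%% x %d", env_name, strategy, pct,
                          spec$replicates))
      }
    }
  }
  rows <- do.call(rbind, rows)
  n_bad <- sum(!rows$terminated)
  if (n_bad > 0)
    warning(sprintf("%d run(s) did not terminate within max_ticks; excluded from summary means",
                    n_bad), call. = FALSE)
  structure(list(rows = rows, summary = summarize_sweep(rows)),
            class = "sweep_result")
}

#' Per-cell summary of sweep rows
#'
#' @param rows The `rows` data frame of a [run_sweep()] result.
#' @return Data frame of per (env, strategy, rational_pct) means and
#'   standard deviations over terminated runs, plus replicate counts.
#' @export
summarize_sweep <- function(rows) {
  ok <- rows[rows$terminated, , drop = FALSE]
  measures <- c("exit_time", "exited_left", "exited_right",
                "max_concurrent_panic", "ever_panicked_rational",
                "ever_panicked_emotional")
  if (nrow(ok) == 0L) {
    empty <- rows[0, c("env", "strategy", "rational_pct")]
    for (m in c(paste0("mean_", measures), paste0("sd_", measures)))
      empty[[m]] <- numeric(0)
    empty$n_runs <- integer(0)
    return(empty)
  }
  by <- ok[, c("env", "strategy", "rational_pct")]
  mean_df <- aggregate(ok[measures], by = by, FUN = mean)
  sd_df <- aggregate(ok[measures], by = by, FUN = sd)
  n_df <- aggregate(list(n_runs = ok$replicate), by = by, FUN = length)
  names(mean_df)[-(1:3)] <- paste0("mean_", measures)
  names(sd_df)[-(1:3)] <- paste0("sd_", measures)
  out <- merge(merge(mean_df, sd_df, by = c("env", "strategy", "rational_pct")),
               n_df, by = c("env", "strategy", "rational_pct"))
  out[order(out$env, out$strategy, out$rational_pct), , drop = FALSE]
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d runs, %d cells\n", nrow(x$rows),
              nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write sweep metrics to CSV
#'
#' Writes the per-run rows as an RFC-4180 CSV with a fixed header (full
#' float precision); for a full `sweep_result` the per-cell summary is
#' written alongside as `<path minus extension>_summary.csv`.
#'
#' @param x A `sweep_result` or its `rows` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  rows <- if (inherits(x, "sweep_result")) x$rows else x
  if (is.null(rows) || nrow(rows) == 0L)
    stop("empty metrics table: nothing to write", call. = FALSE)
  write.csv(rows, path, row.names = FALSE)
  if (inherits(x, "sweep_result")) {
    spath <- sub("\\.csv$", "", path)
    write.csv(x$summary, paste0(spath, "_summary.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read back a metrics CSV
#'
#' @param path CSV path written by [write_metrics_csv()].
#' @return The rows data frame.
#' @export
read_metrics_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Synthetic fixture environments
#'
#' Emits valid map text for small test worlds: `open` (no obstacles, one
#' exit patch centered on each of the west and east walls), `corridor` (a
#' single one-cell-wide passage between the exits), `pocket` (an open room
#' plus a sealed, unreachable walkable region), and `asymmetric` (a partial
#' obstacle wall in front of the right exit, so more than half of the
#' walkable patches are nearer the left exit).
#'
#' @param kind One of `"open"`, `"corridor"`, `"pocket"`, `"asymmetric"`.
#' @param size Side length; at least 7 (at least 9 for `pocket`).
#' @return Character vector of map rows.
#' @export
generate_fixture_world <- function(kind = c("open", "corridor", "pocket",
                                            "asymmetric"), size = 15L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 7L)
    stop("config error: fixture size must be at least 7", call. = FALSE)
  if (kind == "pocket" && size < 9L)
    stop("config error: pocket fixture needs size of at least 9", call. = FALSE)
  mid <- (size + 1L) %/% 2L
  m <- matrix(".", size, size)
  if (kind == "corridor") {
    m[] <- "#"
    m[mid, ] <- "."
  }
  m[mid, 1L] <- "L"
  m[mid, size] <- "R"
  if (kind == "pocket") {
    # 5x5 obstacle ring with a sealed 3x3 walkable interior, top area
    m[2:6, 3:7] <- "#"
    m[3:5, 4:6] <- "."
  }
  if (kind == "asymmetric") {
    len <- round(0.55 * (size - 2L))
    if (len %% 2L == 0L) len <- len + 1L
    len <- min(len, size - 4L)
    half <- (len - 1L) %/% 2L
    m[(mid - half):(mid + half), size - 3L] <- "#"
  }
  apply(m, 1L, paste0, collapse = "")
}

#' Bar chart of a sweep measure
#'
#' Mirrors the standard presentation of sweep results: one panel per
#' rational percentage, environments on the x axis, one bar per strategy.
#' Requires ggplot2.
#'
#' @param sweep A `sweep_result`.
#' @param measure Summary column to plot (without the `mean_` prefix).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, measure = c("exit_time", "exited_left",
                                          "max_concurrent_panic",
                                          "ever_panicked_rational")) {
  measure <- match.arg(measure)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_sweep requires the ggplot2 package", call. = FALSE)
  s <- sweep$summary
  s$.value <- s[[paste0("mean_", measure)]]
  ggplot2::ggplot(s, ggplot2::aes(x = env, y = .value, fill = strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~rational_pct, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "environment", y = paste("mean", measure)) +
    ggplot2::theme_minimal()
}
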