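#' Read and write simulation configurations
#'
#' Configurations are stored as YAML. Unset keys take the full-scale study
#' defaults (N = 400 beads, \eqn{l_p = 5\sigma}, dt = 0.01 \eqn{\tau_B},
#' \eqn{\Delta t = 100\,\tau_B}, run \eqn{10^5\,\tau_B}, SMC spring
#' k = 5 \eqn{\epsilon/\sigma^2} with r0 = 1.6 \eqn{\sigma}, shell 1--4
#' \eqn{\sigma}, jump cap 5 beads, 30 replicates); out-of-range values
#' raise a validation error naming the offending keys.
#'
#' @param path YAML file path.
#' @return `load_config()`: an [sim_config()]. `save_config()`: `path`,
#'   invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(sim_config))
  extra <- setdiff(names(raw), c(known, "field_mode", "slab_gap",
                                 "tether_force"))
  if (length(extra)) {
    abort(paste0("load_config: unknown keys: ", paste(extra, collapse = ", ")))
  }
  fld <- external_field(mode = raw$field_mode %||% "none",
                        slab_gap = raw$slab_gap %||% 3,
                        tether_force = raw$tether_force %||% 0.5)
  raw$field_mode <- raw$slab_gap <- raw$tether_force <- NULL
  raw$field <- fld
  if (!is.null(raw$shell)) raw$shell <- as.numeric(raw$shell)
  do.call(sim_config, raw)
}

#' @rdname load_config
#' @param config An [sim_config()].
#' @param overwrite Allow replacing an existing file.
#' @export
save_config <- function(config, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  x <- unclass(config)
  x$field_mode <- x$field$mode
  x$slab_gap <- x$field$slab_gap
  x$tether_force <- x$field$tether_force
  x$field <- NULL
  x$units <- NULL
  x$shell <- as.numeric(x$shell)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write an event log as CSV
#'
#' One row per capture attempt with the standard columns: replicate, time,
#' success, old_head, new_head, signed_step, candidate_count, gamma,
#' variant.
#'
#' @param sim An `smc_sim` (or event tibble).
#' @param path Output path.
#' @param overwrite Allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(sim, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  ev <- as_events(sim)
  cols <- c("replicate", "time", "success", "old_head", "new_head",
            "signed_step", "candidate_count", "anchor", "gamma", "variant")
  write.csv(ev[, intersect(cols, names(ev))], path, row.names = FALSE)
  invisible(path)
}

#' Trajectory writers
#'
#' `write_xyz()` writes conformations in plain XYZ format (bead count,
#' comment with the time in \eqn{\tau_B}, then one `DNA x y z` record per
#' bead). `write_lammps_dump()` writes a LAMMPS-dump-style text format
#' (`ITEM: TIMESTEP` header, then `id x y z` records). Positions are in
#' reduced units (\eqn{\sigma}); the comment/header says so.
#'
#' @param frames A single conformation (matrix or `smc_polymer`) or a list
#'   of them.
#' @param path Output path.
#' @param times Frame times in \eqn{\tau_B} (recycled from 0, 1, ... if
#'   missing).
#' @param overwrite Allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, times = NULL, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  frames <- as_frame_list(frames)
  times <- times %||% (seq_along(frames) - 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    pos <- frames[[i]]
    writeLines(as.character(nrow(pos)), con)
    writeLines(sprintf("t= %g tau_B, units= sigma", times[i]), con)
    writeLines(sprintf("DNA %.6f %.6f %.6f", pos[, 1], pos[, 2], pos[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
write_lammps_dump <- function(frames, path, times = NULL,
                              overwrite = FALSE) {
  check_overwrite(path, overwrite)
  frames <- as_frame_list(frames)
  times <- times %||% (seq_along(frames) - 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    pos <- frames[[i]]
    lo <- apply(pos, 2, min) - 1
    hi <- apply(pos, 2, max) + 1
    writeLines(c("ITEM: TIMESTEP", as.character(times[i]),
                 "ITEM: NUMBER OF ATOMS", as.character(nrow(pos)),
                 "ITEM: BOX BOUNDS ff ff ff",
                 sprintf("%g %g", lo[1], hi[1]),
                 sprintf("%g %g", lo[2], hi[2]),
                 sprintf("%g %g", lo[3], hi[3]),
                 "ITEM: ATOMS id x y z"), con)
    writeLines(sprintf("%d %.6f %.6f %.6f", seq_len(nrow(pos)),
                       pos[, 1], pos[, 2], pos[, 3]), con)
  }
  invisible(path)
}

#' Read back an XYZ trajectory
#'
#' Minimal reader for files produced by [write_xyz()] (round-trip tests,
#' quick inspection).
#'
#' @param path XYZ file.
#' @return A list of n-by-3 matrices.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(block, "\\s+"))
    m <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    colnames(m) <- c("x", "y", "z")
    out[[length(out) + 1]] <- m
    i <- i + 2 + n
  }
  out
}

#' Run a fully specified experiment and persist its outputs
#'
#' Executes equilibration, loading and the extrusion loop for every
#' replicate of `config`, then writes the event log, the loop trace, the
#' configuration and a run manifest (seed, package version, wall time,
#' file list) into `outdir`. Existing files are never overwritten
#' silently.
#'
#' @param config An [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param overwrite Allow replacing existing outputs.
#' @param write_trajectories Also write the final conformation of each
#'   replicate as XYZ (off by default; event logs carry all statistics).
#' @return The `smc_sim`, invisibly; its outputs are on disk.
#' @export
run_experiment <- function(config, outdir, overwrite = FALSE,
                           write_trajectories = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("events.csv", "trace.csv", "config.yaml",
                               "manifest.json", "summary.json"))
  check_overwrite(paths, overwrite)
  t0 <- Sys.time()
  sim <- simulate_extrusion(config, keep_final = write_trajectories)
  write_event_log(sim, paths[1], overwrite = overwrite)
  write.csv(sim$trace, paths[2], row.names = FALSE)
  save_config(config, paths[3], overwrite = overwrite)
  traj_files <- character()
  if (write_trajectories) {
    for (r in seq_along(sim$final)) {
      f <- file.path(outdir, sprintf("final_rep%03d.xyz", r))
      check_overwrite(f, overwrite)
      write_xyz(sim$final[[r]]$positions, f, times = config$run_time,
                overwrite = overwrite)
      traj_files <- c(traj_files, f)
    }
  }
  g <- as.list(glance(sim))
  g <- lapply(g, function(v) {
    if (is.numeric(v) && !is.finite(v)) as.character(v) else v
  })
  jsonlite::write_json(g, paths[5], auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "smcloop",
    version = as.character(packageVersion("smcloop")),
    seed = config$seed,
    replicates = config$replicates,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = basename(c(paths[1:3], paths[5], traj_files))
  )
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, pretty = TRUE)
  invisible(sim)
}

check_overwrite <- function(paths, overwrite) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  hit <- paths[file.exists(unlist(paths))]
  if (length(hit) && !overwrite) {
    abort(paste0("refusing to overwrite existing output (set overwrite = TRUE): ",
                 paste(hit, collapse = ", ")))
  }
  invisible(TRUE)
}

as_frame_list <- function(frames) {
  if (inherits(frames, "smc_polymer")) return(list(frames$positions))
  if (is.matrix(frames)) return(list(frames))
  lapply(frames, polymer_positions)
}
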