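#' Simulate SMC loop extrusion
#'
#' Full pipeline for one condition: for each replicate, generate a chain,
#' relax and equilibrate it, load an SMC at a random 3D-proximate bead
#' pair, then alternate \eqn{\Delta t} of Brownian dynamics with one
#' capture attempt until `run_time` is reached. Returns the per-attempt
#' event log and the oriented-loop-length trace for every replicate.
#'
#' Replicates are seeded independently from `config$seed`; rerunning with
#' the same configuration reproduces the event log exactly.
#'
#' @param config An [sim_config()] (see [desk_config()] for a reduced
#'   preset).
#' @param replicates Number of replicates (default `config$replicates`).
#' @param keep_final Keep the final conformation of each replicate
#'   (list-column `final`); off by default.
#' @param progress Print one line per replicate.
#' @return An object of class `smc_sim`: a list with
#'   \describe{
#'     \item{events}{tibble, one row per capture attempt: replicate, time
#'       (\eqn{\tau_B} since loading), success, old_head, new_head,
#'       signed_step (change of \eqn{l = n_a - n_h}), abs_step (change of
#'       \eqn{|l|}), candidate_count, anchor, gamma, variant.}
#'     \item{trace}{tibble, one row per attempt time per replicate:
#'       replicate, time, loop_length (signed \eqn{l}).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' \donttest{
#' sim <- simulate_extrusion(desk_config(n_beads = 60, run_time = 1000,
#'                                       equilibration_time = 200,
#'                                       replicates = 2))
#' glance(sim)
#' }
#' @export
simulate_extrusion <- function(config = sim_config(),
                               replicates = config$replicates,
                               keep_final = FALSE, progress = FALSE) {
  events <- vector("list", replicates)
  traces <- vector("list", replicates)
  finals <- if (keep_final) vector("list", replicates) else NULL
  ff <- unclass(config_ff(config))
  for (rep in seq_len(replicates)) {
    pol <- make_polymer(config$n_beads, "random_walk",
                        seed = derive_seed(config$seed, rep, 3),
                        persistence_length = config$persistence_length)
    if (config$field$mode %in% c("slab", "slab+tether")) {
      # start inside the slab; the walls keep it there
      bound <- max(config$field$slab_gap / 2 - 0.5, 0.1)
      z <- pol$positions[, 3]
      if (max(abs(z)) > 0) {
        pol$positions[, 3] <- z / max(1, max(abs(z)) / (0.9 * bound))
      }
    }
    pol <- equilibrate(pol, config, replicate = rep)
    smc <- load_smc(pol, config, replicate = rep)
    res <- cpp_extrude(
      polymer_positions(pol), ff, smc_to_cpp(smc),
      run_time = config$run_time, dt = config$dt,
      attempt_interval = config$attempt_interval,
      field = field_to_cpp(config$field),
      temperature = config$temperature, friction = config$friction,
      seed = config$seed, replicate = rep,
      scheme = if (identical(config$integrator, "euler")) 1L else 0L
    )
    a <- smc$anchor
    events[[rep]] <- tibble(
      replicate = rep, time = res$time,
      success = as.logical(res$success),
      old_head = res$old_head, new_head = res$new_head,
      signed_step = res$signed_step,
      abs_step = abs(a - res$new_head) - abs(a - res$old_head),
      candidate_count = res$candidate_count,
      anchor = a, gamma = config$gamma, variant = config$variant
    )
    traces[[rep]] <- tibble(
      replicate = rep, time = res$trace_time, loop_length = res$trace_l
    )
    if (keep_final) {
      p2 <- pol
      p2$positions <- res$positions
      colnames(p2$positions) <- c("x", "y", "z")
      finals[[rep]] <- p2
    }
    if (progress) {
      message(sprintf("replicate %d/%d: |l| %d -> %d", rep, replicates,
                      abs(smc$anchor - smc$head),
                      abs(smc$anchor - res$final_head)))
    }
  }
  structure(
    list(events = dplyr::bind_rows(events), trace = dplyr::bind_rows(traces),
         config = config, final = finals),
    class = "smc_sim"
  )
}

#' @export
print.smc_sim <- function(x, ...) {
  g <- glance(x)
  cat("<smc_sim> gamma =", x$config$gamma, "deg |", x$config$variant, "|",
      max(x$events$replicate), "replicates x",
      sum(x$events$replicate == 1), "attempts\n")
  cat(sprintf("  success %.1f%% | mean step %+.2f beads | final <|l|> %.1f beads\n",
              100 * g$success_probability, g$mean_step, g$mean_final_loop))
  invisible(x)
}

#' @rdname simulate_extrusion
#' @param x An `smc_sim`.
#' @param ... Unused.
#' @return `tidy.smc_sim()`: the event log tibble. `glance.smc_sim()`: a
#'   one-row tibble with pooled success probability, mean (signed) step in
#'   beads, forward:backward step-count ratio and mean final loop size.
#' @export
tidy.smc_sim <- function(x, ...) x$events

#' @rdname simulate_extrusion
#' @export
glance.smc_sim <- function(x, ...) {
  st <- step_statistics(x)
  fin <- x$trace |>
    dplyr::group_by(.data$replicate) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  dplyr::mutate(st$summary, mean_final_loop = mean(abs(fin$loop_length)))
}
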