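#' Sweep the grabbing angle
#'
#' Runs the full extrusion pipeline at each grabbing angle and assembles
#' the per-angle statistics behind the step-size / success-rate trade-off:
#' narrower angles give larger, more rectified steps but fail to find a
#' segment more often; wider angles step more reliably but shorter and
#' less directionally. The trade-off produces an optimum of the mean
#' extrusion velocity at an intermediate angle.
#'
#' @param config Base [sim_config()]; its `gamma` is ignored.
#' @param gammas Grabbing angles in degrees.
#' @param replicates Replicates per angle.
#' @param keep_sims Keep each full `smc_sim` in a list-column (memory!).
#' @param progress Print one line per angle.
#' @return An object of class `smc_sweep`: a tibble with one row per
#'   angle (gamma, n_attempts, success_probability, mean_step,
#'   forward_backward_ratio, velocity, velocity_se, velocity_kbp_s,
#'   growth_exponent and list-columns histogram, rms_curve), carrying the
#'   optimum angle in `attr(, "argmax_gamma")`.
#' @export
gamma_sweep <- function(config = sim_config(),
                        gammas = c(60, 120, 180, 240, 300, 360),
                        replicates = config$replicates,
                        keep_sims = FALSE, progress = FALSE) {
  if (length(gammas) < 1) abort("gamma_sweep: need at least one angle")
  rows <- purrr::map(gammas, function(g) {
    cfg <- config
    cfg$gamma <- g
    cfg <- validate_config(cfg)
    sim <- simulate_extrusion(cfg, replicates = replicates)
    st <- step_statistics(sim)
    vel <- extrusion_velocity(sim)
    rms <- rms_extruded_length(sim, boot = 0)
    if (progress) {
      message(sprintf(
        "gamma = %3d: success %.2f, s = %+.2f beads, v = %.4f beads/tau_B",
        g, st$summary$success_probability, st$summary$mean_step,
        vel$velocity))
    }
    tibble(
      gamma = g,
      n_attempts = st$summary$n_attempts,
      n_success = st$summary$n_success,
      success_probability = st$summary$success_probability,
      mean_step = st$summary$mean_step,
      forward_backward_ratio = st$summary$forward_backward_ratio,
      velocity = vel$velocity, velocity_se = vel$se,
      velocity_kbp_s = vel$velocity_kbp_s,
      growth_exponent = vel$growth_exponent,
      histogram = list(st$histogram),
      rms_curve = list(rms),
      sim = if (keep_sims) list(sim) else list(NULL)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!keep_sims) out$sim <- NULL
  out <- structure(out, class = c("smc_sweep", class(tibble())))
  attr(out, "argmax_gamma") <- out$gamma[which.max(out$velocity)]
  attr(out, "config") <- config
  out
}

#' @rdname gamma_sweep
#' @param x An `smc_sweep`.
#' @param ... Unused.
#' @return `glance.smc_sweep()`: one-row tibble with the
#'   velocity-optimal angle and its velocity.
#' @export
glance.smc_sweep <- function(x, ...) {
  i <- which.max(x$velocity)
  tibble(argmax_gamma = x$gamma[i], max_velocity = x$velocity[i],
         max_velocity_kbp_s = x$velocity_kbp_s[i], n_gammas = nrow(x))
}

#' @rdname gamma_sweep
#' @return `tidy.smc_sweep()`: the sweep in long form, one row per
#'   (gamma, statistic).
#' @export
tidy.smc_sweep <- function(x, ...) {
  x |>
    dplyr::select("gamma", "success_probability", "mean_step",
                  "forward_backward_ratio", "velocity",
                  "growth_exponent") |>
    tidyr::pivot_longer(-"gamma", names_to = "statistic",
                        values_to = "value")
}

#' Export a sweep as tidy CSV
#'
#' One row per (gamma, statistic) pair; histograms are exported alongside
#' as (gamma, step, prob) rows in a second file if `histogram_path` is
#' given.
#'
#' @param sweep An `smc_sweep`.
#' @param path Output CSV path.
#' @param histogram_path Optional CSV path for the step histograms.
#' @param overwrite Allow replacing existing files.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path, histogram_path = NULL,
                            overwrite = FALSE) {
  check_overwrite(c(path, histogram_path), overwrite)
  write.csv(tidy(sweep), path, row.names = FALSE)
  if (!is.null(histogram_path)) {
    h <- sweep |>
      dplyr::select("gamma", "histogram") |>
      tidyr::unnest("histogram")
    write.csv(h, histogram_path, row.names = FALSE)
  }
  invisible(path)
}
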