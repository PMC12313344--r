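#' Root-mean-squared extruded length over time
#'
#' Pointwise \eqn{\langle l\rangle(t) = \langle [n_a - n_h]^2
#' \rangle^{1/2}} across replicates, with bootstrap standard errors
#' (resampling replicates).
#'
#' @param trace A trace tibble (replicate, time, loop_length) or an
#'   [simulate_extrusion()] result.
#' @param boot Bootstrap resamples for the standard error (0 to skip).
#' @return A tibble: time, rms, se, n_replicates.
#' @export
rms_extruded_length <- function(trace, boot = 100) {
  tr <- as_trace(trace)
  counts <- dplyr::count(tr, .data$time)
  if (length(unique(counts$n)) != 1) {
    abort("rms_extruded_length: replicates do not share a common time grid")
  }
  nrep <- counts$n[1]
  if (nrep < 2) {
    abort("rms_extruded_length: need at least 2 replicates")
  }
  wide <- tr |>
    dplyr::arrange(.data$time, .data$replicate) |>
    tidyr::pivot_wider(names_from = "replicate",
                       values_from = "loop_length")
  times <- wide$time
  m <- as.matrix(wide[, -1])^2
  rms <- sqrt(rowMeans(m))
  se <- rep(NA_real_, length(rms))
  if (boot > 0) {
    bs <- replicate(boot, {
      sqrt(rowMeans(m[, sample.int(ncol(m), replace = TRUE), drop = FALSE]))
    })
    se <- apply(bs, 1, sd)
  }
  tibble(time = times, rms = rms, se = se, n_replicates = nrep)
}

#' Fit the growth exponent of an RMS-length curve
#'
#' Least-squares slope of \eqn{\log\langle l\rangle} versus \eqn{\log t}
#' over a time window. An isotropic (\eqn{\gamma = 360^\circ}) run gives
#' an exponent near 0.5 (random walk); rectified extrusion approaches 1
#' (ballistic growth).
#'
#' @param curve Output of [rms_extruded_length()] (or any tibble with
#'   `time` and `rms`).
#' @param window c(min, max) time window; default the last decade of the
#'   curve, which skips the loading transient.
#' @return An object of class `smc_powerfit`; see [tidy()]/[glance()].
#' @export
fit_scaling_exponent <- function(curve, window = NULL) {
  t_max <- max(curve$time)
  window <- window %||% c(0.1 * t_max, t_max)
  sel <- curve$time >= window[1] & curve$time <= window[2] & curve$time > 0
  d <- curve[sel, ]
  if (nrow(d) < 3) abort("fit_scaling_exponent: window contains < 3 points")
  if (any(d$rms <= 0)) {
    abort("fit_scaling_exponent: non-positive RMS values in window")
  }
  fit <- lm(log(rms) ~ log(time), data = d)
  # vcov warns on numerically perfect fits (se = 0); that is fine here
  se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2]))
  structure(
    list(exponent = unname(coef(fit)[2]),
         se = se,
         intercept = unname(coef(fit)[1]),
         window = window, n = nrow(d), fit = fit),
    class = "smc_powerfit"
  )
}

#' @export
print.smc_powerfit <- function(x, ...) {
  cat(sprintf("<smc_powerfit> exponent %.3f +/- %.3f over t in [%g, %g] (%d points)\n",
              x$exponent, x$se, x$window[1], x$window[2], x$n))
  invisible(x)
}

#' @rdname fit_scaling_exponent
#' @param x An `smc_powerfit`.
#' @param ... Unused.
#' @export
tidy.smc_powerfit <- function(x, ...) {
  tibble(term = c("intercept", "exponent"),
         estimate = c(x$intercept, x$exponent),
         std.error = c(NA_real_, x$se))
}

#' @rdname fit_scaling_exponent
#' @export
glance.smc_powerfit <- function(x, ...) {
  tibble(exponent = x$exponent, std.error = x$se,
         window_min = x$window[1], window_max = x$window[2], n = x$n)
}

#' Step statistics from an event log
#'
#' Pools capture attempts and computes: the success probability
#' (successful attempts / total attempts), the mean step size
#' \eqn{s = \sum_i \mathrm{sign}(i) S_i / N} with \eqn{S_i} the i-th step
#' size, the sign positive for loop-growing (forward) steps and \eqn{N}
#' the number of successful steps, the signed step-size histogram (1-bead
#' bins, also in nm at 10 nm/bead) and the forward:backward step-count
#' ratio.
#'
#' @param events An event tibble from [simulate_extrusion()] (or the
#'   `smc_sim` itself). Steps are measured as changes of \eqn{|l|}, so the
#'   `abs_step`/`anchor` columns are used.
#' @param units A [unit_system()] for the nm conversion.
#' @return An object of class `smc_step_stats`: list with `summary`
#'   (one-row tibble) and `histogram` (tibble: step, step_nm, n, prob).
#'   With zero successful steps the ratio and mean step are `NA`; with no
#'   backward steps the ratio is `Inf`.
#' @export
step_statistics <- function(events, units = unit_system()) {
  ev <- as_events(events)
  n_att <- nrow(ev)
  if (n_att == 0) abort("step_statistics: empty event log")
  suc <- dplyr::filter(ev, .data$success)
  n_suc <- nrow(suc)
  p_suc <- n_suc / n_att
  if (n_suc > 0) {
    steps <- suc$abs_step
    mean_step <- mean(steps)
    n_fwd <- sum(steps > 0)
    n_bwd <- sum(steps < 0)
    fb <- if (n_bwd == 0) Inf else n_fwd / n_bwd
    hist <- suc |>
      dplyr::count(step = .data$abs_step) |>
      dplyr::mutate(step_nm = beads_to_nm(.data$step, units),
                    prob = .data$n / sum(.data$n)) |>
      dplyr::select("step", "step_nm", "n", "prob")
  } else {
    mean_step <- NA_real_
    fb <- NA_real_
    n_fwd <- 0L
    n_bwd <- 0L
    hist <- tibble(step = integer(), step_nm = numeric(), n = integer(),
                   prob = numeric())
  }
  structure(
    list(summary = tibble(
      n_attempts = n_att, n_success = n_suc,
      success_probability = p_suc, mean_step = mean_step,
      mean_step_nm = beads_to_nm(mean_step, units),
      n_forward = n_fwd, n_backward = n_bwd,
      forward_backward_ratio = fb
    ), histogram = hist),
    class = "smc_step_stats"
  )
}

#' @export
print.smc_step_stats <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<smc_step_stats> %d attempts | success %.1f%% | s = %+.2f beads (%+.0f nm) | fwd:bwd %s\n",
              s$n_attempts, 100 * s$success_probability, s$mean_step,
              s$mean_step_nm,
              if (is.finite(s$forward_backward_ratio)) {
                sprintf("%.2f", s$forward_backward_ratio)
              } else {
                as.character(s$forward_backward_ratio)
              }))
  invisible(x)
}

#' @rdname step_statistics
#' @param x An `smc_step_stats`.
#' @param ... Unused.
#' @export
tidy.smc_step_stats <- function(x, ...) x$histogram

#' @rdname step_statistics
#' @export
glance.smc_step_stats <- function(x, ...) x$summary

#' Location of the large forward-step peak
#'
#' The mode of the forward step-size distribution restricted to steps of at
#' least `min_beads` beads, in beads and nm. This is the statistic that is
#' compared with the ~50 nm steps seen in single-molecule experiments.
#'
#' @param x An `smc_step_stats`, event tibble or `smc_sim`.
#' @param min_beads Smallest step counted as "large".
#' @param units A [unit_system()].
#' @return A one-row tibble: mode_beads, mode_nm, n_large.
#' @export
large_step_mode <- function(x, min_beads = 2, units = unit_system()) {
  st <- if (inherits(x, "smc_step_stats")) x else step_statistics(x, units)
  h <- dplyr::filter(st$histogram, .data$step >= min_beads)
  if (nrow(h) == 0) {
    return(tibble(mode_beads = NA_integer_, mode_nm = NA_real_,
                  n_large = 0L))
  }
  best <- h$step[which.max(h$n)]
  tibble(mode_beads = as.integer(best),
         mode_nm = beads_to_nm(best, units), n_large = sum(h$n))
}

#' Extrusion velocity from loop traces
#'
#' Least-squares slope of the replicate-mean \eqn{|l|(t)} over a window of
#' the run (default 10--60% of the total time, which excludes the loading
#' transient and end-of-chain saturation), with a bootstrap standard error
#' over replicates. A log-log growth exponent well below 1 over the same
#' window flags a non-linear (random-walk-like) regime, in which the
#' reported slope is not an extrusion velocity in any meaningful sense.
#'
#' @param trace A trace tibble or `smc_sim`.
#' @param window Fractions c(lo, hi) of the total duration to fit over.
#' @param boot Bootstrap resamples.
#' @param units A [unit_system()] for the physical conversion
#'   (beads/\eqn{\tau_B} times 30 bp/bead over 2.3e-4 s/\eqn{\tau_B}).
#' @return One-row tibble: velocity (beads/\eqn{\tau_B}), se, velocity_bp_s,
#'   velocity_kbp_s, growth_exponent, nonlinear (logical).
#' @export
extrusion_velocity <- function(trace, window = c(0.1, 0.6), boot = 100,
                               units = unit_system()) {
  tr <- as_trace(trace)
  t_max <- max(tr$time)
  lo <- window[1] * t_max
  hi <- window[2] * t_max
  mean_abs <- tr |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(m = mean(abs(.data$loop_length)), .groups = "drop")
  sel <- mean_abs$time >= lo & mean_abs$time <= hi
  d <- mean_abs[sel, ]
  if (nrow(d) < 3) {
    # very short runs: fall back to the whole post-loading range
    d <- mean_abs[mean_abs$time > 0, ]
    lo <- min(d$time)
    hi <- max(d$time)
  }
  if (nrow(d) < 3) abort("extrusion_velocity: fit window contains < 3 points")
  v <- unname(coef(lm(m ~ time, data = d))[2])
  # growth exponent over the same window to flag non-linearity
  dpos <- d[d$m > 0 & d$time > 0, ]
  expn <- if (nrow(dpos) >= 3) {
    unname(coef(lm(log(m) ~ log(time), data = dpos))[2])
  } else {
    NA_real_
  }
  se <- NA_real_
  if (boot > 0) {
    reps <- unique(tr$replicate)
    vs <- replicate(boot, {
      pick <- sample(reps, replace = TRUE)
      trb <- dplyr::bind_rows(lapply(seq_along(pick), function(i) {
        dplyr::mutate(tr[tr$replicate == pick[i], ], replicate = i)
      }))
      mb <- trb |>
        dplyr::group_by(.data$time) |>
        dplyr::summarise(m = mean(abs(.data$loop_length)), .groups = "drop")
      db <- mb[mb$time >= lo & mb$time <= hi, ]
      if (nrow(db) < 3) db <- mb[mb$time > 0, ]
      unname(coef(lm(m ~ time, data = db))[2])
    })
    se <- sd(vs)
  }
  tibble(velocity = v, se = se,
         velocity_bp_s = velocity_to_bp_per_s(v, units),
         velocity_kbp_s = velocity_to_kbp_per_s(v, units),
         growth_exponent = expn,
         nonlinear = is.finite(expn) && expn < 0.8)
}

# ---- coercion helpers -------------------------------------------------

as_trace <- function(x) {
  if (inherits(x, "smc_sim")) return(x$trace)
  if (is.data.frame(x) &&
      all(c("replicate", "time", "loop_length") %in% names(x))) {
    return(x)
  }
  abort("expected an smc_sim or a trace tibble (replicate, time, loop_length)")
}

as_events <- function(x) {
  if (inherits(x, "smc_sim")) return(x$events)
  if (is.data.frame(x) && all(c("success", "abs_step") %in% names(x))) {
    return(x)
  }
  abort("expected an smc_sim or an event tibble (success, abs_step, ...)")
}
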