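#' Plot loop-extrusion traces
#'
#' Spaghetti plot of the oriented loop length \eqn{l(t)} (or its
#' magnitude) per replicate.
#'
#' @param object An `smc_sim`.
#' @param absolute Plot \eqn{|l|} instead of signed \eqn{l}.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smc_sim <- function(object, absolute = TRUE, ...) {
  tr <- object$trace
  if (absolute) tr <- dplyr::mutate(tr, loop_length = abs(.data$loop_length))
  ggplot2::ggplot(tr, ggplot2::aes(.data$time, .data$loop_length,
                                   group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(
      x = "time (tau_B)",
      y = if (absolute) "extruded length |l| (beads)" else "loop length l (beads)",
      title = sprintf("gamma = %g deg, %s", object$config$gamma,
                      object$config$variant)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a grabbing-angle sweep
#'
#' `type = "tradeoff"` shows success probability and mean step size versus
#' gamma (the two opposing trends); `"velocity"` the extrusion-velocity
#' optimum; `"histogram"` the per-gamma signed step-size distributions;
#' `"rms"` the RMS extruded-length curves on log-log axes.
#'
#' @param object An `smc_sweep`.
#' @param type One of "tradeoff", "velocity", "histogram", "rms".
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smc_sweep <- function(object, type = c("tradeoff", "velocity",
                                                "histogram", "rms"), ...) {
  type <- match.arg(type)
  if (type == "tradeoff") {
    d <- object |>
      dplyr::select("gamma", "success_probability", "mean_step") |>
      tidyr::pivot_longer(-"gamma")
    ggplot2::ggplot(d, ggplot2::aes(.data$gamma, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::facet_wrap(~name, scales = "free_y") +
      ggplot2::labs(x = "grabbing angle gamma (deg)", y = NULL) +
      ggplot2::theme_minimal()
  } else if (type == "velocity") {
    ggplot2::ggplot(object, ggplot2::aes(.data$gamma, .data$velocity)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data$velocity - .data$velocity_se,
        ymax = .data$velocity + .data$velocity_se), width = 8) +
      ggplot2::labs(x = "grabbing angle gamma (deg)",
                    y = "extrusion velocity (beads/tau_B)") +
      ggplot2::theme_minimal()
  } else if (type == "histogram") {
    h <- object |>
      dplyr::select("gamma", "histogram") |>
      tidyr::unnest("histogram")
    ggplot2::ggplot(h, ggplot2::aes(.data$step, .data$prob)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~gamma) +
      ggplot2::labs(x = "step size (beads; +: loop grows)",
                    y = "probability") +
      ggplot2::theme_minimal()
  } else {
    r <- object |>
      dplyr::select("gamma", "rms_curve") |>
      tidyr::unnest("rms_curve") |>
      dplyr::filter(.data$time > 0, .data$rms > 0)
    ggplot2::ggplot(r, ggplot2::aes(.data$time, .data$rms,
                                    colour = factor(.data$gamma))) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "time (tau_B)", y = "RMS extruded length (beads)",
                    colour = "gamma (deg)") +
      ggplot2::theme_minimal()
  }
}

#' Step-size histogram plot
#'
#' @param stats An `smc_step_stats` (or event tibble / `smc_sim`).
#' @param nm Label the x axis in nm instead of beads.
#' @return A ggplot.
#' @export
plot_step_histogram <- function(stats, nm = FALSE) {
  st <- if (inherits(stats, "smc_step_stats")) stats else step_statistics(stats)
  h <- st$histogram
  xvar <- if (nm) "step_nm" else "step"
  ggplot2::ggplot(h, ggplot2::aes(.data[[xvar]], .data$prob)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = if (nm) "step size (nm)" else "step size (beads)",
                  y = "probability") +
    ggplot2::theme_minimal()
}
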