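#' Reduced-unit system and physical mapping
#'
#' All simulation arithmetic happens in reduced units: one bead diameter
#' \eqn{\sigma} is the length unit, the thermal energy \eqn{k_BT} the energy
#' unit and the Brownian time \eqn{\tau_B} of a single bead the time unit.
#' This object stores the mapping to physical units used only when reporting
#' observables: a bead is 10 nm of DNA (30 bp), and one \eqn{\tau_B}
#' corresponds to 2.3e-4 s (so that an attempt interval of 100 \eqn{\tau_B}
#' is 0.023 s and a 1e5 \eqn{\tau_B} run about 23 s).
#'
#' @param sigma_nm Bead diameter in nanometres.
#' @param bp_per_bead Base pairs of DNA per bead.
#' @param tau_B_seconds Physical duration of one Brownian time, in seconds.
#' @return An object of class `smc_units` (a named list).
#' @examples
#' u <- unit_system()
#' beads_to_nm(5, u)          # a 5-bead step in nm
#' velocity_to_bp_per_s(0.01, u)  # beads/tau_B -> bp/s
#' @export
unit_system <- function(sigma_nm = 10, bp_per_bead = 30,
                        tau_B_seconds = 2.3e-4) {
  stopifnot(sigma_nm > 0, bp_per_bead > 0, tau_B_seconds > 0)
  structure(
    list(sigma_nm = sigma_nm, bp_per_bead = bp_per_bead,
         tau_B_seconds = tau_B_seconds, epsilon = 1, tau_B = 1),
    class = "smc_units"
  )
}

#' Convert bead counts to nanometres of DNA contour
#' @param beads Length in beads.
#' @param units A [unit_system()].
#' @return Length in nm.
#' @export
beads_to_nm <- function(beads, units = unit_system()) beads * units$sigma_nm

#' Convert bead counts to base pairs
#' @inheritParams beads_to_nm
#' @return Length in bp.
#' @export
beads_to_bp <- function(beads, units = unit_system()) beads * units$bp_per_bead

#' Convert an extrusion velocity from reduced to physical units
#'
#' @param v Velocity in beads per \eqn{\tau_B}.
#' @param units A [unit_system()].
#' @return Velocity in bp/s.
#' @export
velocity_to_bp_per_s <- function(v, units = unit_system()) {
  v * units$bp_per_bead / units$tau_B_seconds
}

#' @rdname velocity_to_bp_per_s
#' @return `velocity_to_kbp_per_s()`: velocity in kbp/s.
#' @export
velocity_to_kbp_per_s <- function(v, units = unit_system()) {
  velocity_to_bp_per_s(v, units) / 1000
}

#' Convert simulation time to seconds
#' @param t Time in \eqn{\tau_B}.
#' @param units A [unit_system()].
#' @return Time in seconds.
#' @export
tau_to_seconds <- function(t, units = unit_system()) t * units$tau_B_seconds
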