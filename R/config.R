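#' Simulation configuration
#'
#' Collects every parameter of a loop-extrusion run. Defaults are the
#' full-scale study conditions: a 400-bead chain (about 12 kbp), grabbing
#' angle \eqn{\gamma = 60^\circ}, integration timestep
#' \eqn{dt = 0.01\,\tau_B}, capture attempts every
#' \eqn{\Delta t = 100\,\tau_B}, a production run of \eqn{10^5\,\tau_B}
#' (about 23 s) and 30 replicates. [desk_config()] provides a reduced
#' preset for interactive work and testing.
#'
#' @param n_beads Chain length in beads.
#' @param gamma Grabbing angle in degrees, in (0, 360]. 360 is the
#'   isotropic (spherically symmetric) capture limit.
#' @param variant SMC structural variant: `"two_spring_asym"` (baseline:
#'   two springs, capture axis anchor-to-head), `"one_spring"`,
#'   `"barycentre_axis"` (two springs, cone apex at the barycentre of the
#'   bonded beads), `"dihedral_asym"` (one spring plus asymmetric torsion
#'   penalty), `"dihedral_sym"` (two springs plus symmetric torsion
#'   penalty).
#' @param run_time Production duration in \eqn{\tau_B}.
#' @param attempt_interval Interval \eqn{\Delta t} between capture attempts,
#'   in \eqn{\tau_B}.
#' @param dt Integration timestep in \eqn{\tau_B} (at most 0.01).
#' @param integrator `"baoab"` (default): inertial Langevin dynamics with
#'   unit mass and friction, BAOAB splitting, stable at dt = 0.01 with the
#'   default bond stiffness; diffusive with \eqn{D = k_BT/\xi} on every
#'   timescale beyond about one \eqn{\tau_B}, far below the attempt
#'   interval. `"euler"`: the strict overdamped Brownian update
#'   (displacement \eqn{(F/\xi)dt} plus Gaussian noise of variance
#'   \eqn{2k_BT dt/\xi} per coordinate); the stiff FENE+WCA bond
#'   (curvature \eqn{\sim 10^3\,\epsilon/\sigma^2}) limits it to
#'   \eqn{dt \lesssim 5\times10^{-4}}, enforced by validation.
#' @param equilibration_time Pre-loading relaxation in \eqn{\tau_B}.
#' @param replicates Number of independent replicates.
#' @param persistence_length DNA persistence length in \eqn{\sigma}.
#' @param smc_k,smc_r0 SMC spring constant (\eqn{\epsilon/\sigma^2},
#'   sweepable over 2--8) and rest length (\eqn{\sigma}).
#' @param shell Radial capture shell, c(min, max) in \eqn{\sigma}
#'   (hinge reach 10--40 nm).
#' @param jump_cap Maximum 1D head displacement per capture, in beads
#'   (default 5, robustness alternative 20).
#' @param field An [external_field()].
#' @param temperature,friction Reduced temperature (\eqn{k_BT}) and
#'   per-bead drag; both 1 by default, which defines \eqn{\tau_B}.
#' @param seed Base integer seed; all randomness derives from it.
#' @param cone_orientation `"forward"` keeps beads whose angle from the
#'   anchor-to-head axis is at most \eqn{\gamma/2} (the physically
#'   consistent rule, reducing to the full shell at \eqn{\gamma = 360});
#'   `"printed"` inverts the inequality and is retained only for audit.
#' @param units A [unit_system()].
#' @return An object of class `smc_config`.
#' @examples
#' cfg <- desk_config(gamma = 120, replicates = 2, run_time = 500)
#' cfg$gamma
#' @export
sim_config <- function(n_beads = 400, gamma = 60,
                       variant = c("two_spring_asym", "one_spring",
                                   "barycentre_axis", "dihedral_asym",
                                   "dihedral_sym"),
                       run_time = 1e5, attempt_interval = 100, dt = 0.01,
                       integrator = c("baoab", "euler"),
                       equilibration_time = 1e4, replicates = 30,
                       persistence_length = 5, smc_k = 5, smc_r0 = 1.6,
                       shell = c(1, 4), jump_cap = 5,
                       field = external_field(), temperature = 1,
                       friction = 1, seed = 1,
                       cone_orientation = c("forward", "printed"),
                       units = unit_system()) {
  variant <- match.arg(variant)
  integrator <- match.arg(integrator)
  cone_orientation <- match.arg(cone_orientation)
  cfg <- structure(
    list(n_beads = n_beads, gamma = gamma, variant = variant,
         run_time = run_time, attempt_interval = attempt_interval, dt = dt,
         integrator = integrator,
         equilibration_time = equilibration_time, replicates = replicates,
         persistence_length = persistence_length,
         smc_k = smc_k, smc_r0 = smc_r0, shell = shell,
         jump_cap = jump_cap, field = field, temperature = temperature,
         friction = friction, seed = seed,
         cone_orientation = cone_orientation, units = units),
    class = "smc_config"
  )
  validate_config(cfg)
}

#' @rdname sim_config
#' @param ... Overrides passed on to [sim_config()].
#' @export
desk_config <- function(...) {
  defaults <- list(n_beads = 200, run_time = 1e4, equilibration_time = 2e3,
                   replicates = 10)
  args <- list(...)
  sim_config_args <- utils::modifyList(defaults, args)
  do.call(sim_config, sim_config_args)
}

validate_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, key, msg) {
    if (!isTRUE(ok)) problems <<- c(problems, paste0(key, ": ", msg))
  }
  chk(is.numeric(cfg$n_beads) && cfg$n_beads >= 10, "n_beads",
      "need at least 10 beads")
  chk(is.numeric(cfg$gamma) && cfg$gamma > 0 && cfg$gamma <= 360, "gamma",
      "grabbing angle must lie in (0, 360] degrees")
  chk(cfg$dt > 0, "dt", "timestep must be positive")
  chk(cfg$dt <= 0.0100000001, "dt",
      "timestep must not exceed 0.01 tau_B at default stiffness")
  if (identical(cfg$integrator, "euler")) {
    chk(cfg$dt <= 5.0000001e-4, "dt",
        "the overdamped Euler scheme is unstable above ~5e-4 tau_B at default bond stiffness; use integrator = 'baoab' or a smaller dt")
  }
  chk(cfg$attempt_interval > 0 &&
        abs(cfg$attempt_interval / cfg$dt -
              round(cfg$attempt_interval / cfg$dt)) < 1e-6,
      "attempt_interval", "must be a positive multiple of dt")
  chk(cfg$run_time >= 0, "run_time", "must be non-negative")
  chk(cfg$equilibration_time >= 0, "equilibration_time",
      "must be non-negative")
  chk(cfg$replicates >= 1, "replicates", "need at least one replicate")
  chk(cfg$persistence_length > 0, "persistence_length", "must be positive")
  chk(cfg$smc_k > 0, "smc_k", "must be positive")
  chk(cfg$smc_r0 > 0, "smc_r0", "must be positive")
  chk(length(cfg$shell) == 2 && cfg$shell[1] > 0 &&
        cfg$shell[2] > cfg$shell[1], "shell",
      "need 0 < min < max")
  chk(cfg$jump_cap >= 1, "jump_cap", "must be at least 1 bead")
  chk(cfg$temperature > 0, "temperature", "must be positive")
  chk(cfg$friction > 0, "friction", "must be positive")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed) &&
        abs(cfg$seed) < 2^31, "seed", "must be a 32-bit integer")
  chk(inherits(cfg$field, "smc_field"), "field",
      "must be an external_field()")
  if (identical(cfg$field$mode, "slab") ||
      identical(cfg$field$mode, "slab+tether")) {
    chk(cfg$field$slab_gap >= 2, "field$slab_gap",
        "slab gap must be at least 2 sigma")
  }
  if (length(problems)) {
    abort(paste0("invalid configuration:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  cfg
}

#' External field: slab confinement and end tethering
#'
#' `mode = "slab"` confines all beads between two walls at
#' \eqn{z = \pm} `slab_gap`/2 (harmonic restoring force beyond a
#' half-bead margin), emulating quasi-2D conditions such as surface
#' deposition. `mode = "tether"` pulls the two chain ends apart with a
#' constant force along x, emulating tethered/stretched DNA assays.
#'
#' @param mode One of "none", "slab", "tether", "slab+tether".
#' @param slab_gap Wall separation in \eqn{\sigma} (default 3; with the
#'   half-bead wall margin this leaves one bead diameter of free vertical
#'   range, quasi-2D relative to the 4\eqn{\sigma} capture reach;
#'   configurable, as no reference value exists for the "narrow slab").
#' @param tether_force Constant force on each end bead in
#'   \eqn{\epsilon/\sigma} (1 \eqn{\epsilon/\sigma} is about 0.4 pN).
#' @return An object of class `smc_field`.
#' @export
external_field <- function(mode = c("none", "slab", "tether", "slab+tether"),
                           slab_gap = 3, tether_force = 0.5) {
  mode <- match.arg(mode)
  if (slab_gap < 2 && mode %in% c("slab", "slab+tether")) {
    abort("external_field: slab_gap must be at least 2 sigma")
  }
  if (tether_force < 0) abort("external_field: tether_force must be >= 0")
  structure(list(mode = mode, slab_gap = slab_gap,
                 tether_force = tether_force),
            class = "smc_field")
}

# internal: convert to what the kernel expects
field_to_cpp <- function(field) {
  if (is.null(field)) return(NULL)
  list(mode = field$mode, slab_gap = field$slab_gap,
       tether_force = field$tether_force)
}

config_ff <- function(cfg) {
  ff_params(kp_prefactor = cfg$persistence_length,
            smc_k = cfg$smc_k, smc_r0 = cfg$smc_r0)
}

variant_id <- function(variant) {
  match(variant, c("two_spring_asym", "one_spring", "barycentre_axis",
                   "dihedral_asym", "dihedral_sym")) - 1L
}

#' @export
print.smc_config <- function(x, ...) {
  cat("<smc_config> N =", x$n_beads, "beads | gamma =", x$gamma,
      "deg |", x$variant, "\n")
  cat("  run", format(x$run_time, big.mark = ","), "tau_B, attempts every",
      x$attempt_interval, "tau_B, dt =", x$dt, "| replicates:",
      x$replicates, "| seed:", x$seed, "\n")
  if (x$field$mode != "none") cat("  field:", x$field$mode, "\n")
  invisible(x)
}
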