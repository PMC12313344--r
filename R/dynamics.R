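#' Advance a polymer by Langevin dynamics
#'
#' Integrates the Langevin equation with the scheme selected in the
#' configuration. The default BAOAB integrator carries unit bead mass and
#' friction, so velocities decorrelate within one \eqn{\tau_B} and the
#' motion is diffusive with \eqn{D = k_BT/\xi = 1\,\sigma^2/\tau_B} (the
#' definition of the Brownian time) on every timescale that matters here.
#' The `"euler"` scheme is the strict overdamped Brownian update: each
#' bead moves by \eqn{(F/\xi)\,dt} plus a Gaussian displacement of
#' variance \eqn{2 k_BT\,dt/\xi} per coordinate; it requires a much
#' smaller timestep against the stiff bonds (see [sim_config()]).
#'
#' @param polymer An [make_polymer()] object.
#' @param config An [sim_config()]; supplies dt, temperature, friction,
#'   force-field constants and the external field.
#' @param duration Simulated time in \eqn{\tau_B}; 0 returns the input
#'   unchanged.
#' @param smc Optional [load_smc()] state whose springs/torsion terms act
#'   during the run (no capture attempts are made here; see
#'   [simulate_extrusion()]).
#' @param replicate,stream Replicate id and RNG stream id, combined with
#'   `config$seed`; identical values reproduce the trajectory bitwise.
#' @param sample_every If positive, also return conformations sampled every
#'   `sample_every` \eqn{\tau_B}.
#' @return The advanced `smc_polymer`; if `sample_every > 0`, a list with
#'   elements `polymer`, `samples` (list of matrices) and `times`.
#' @export
run_dynamics <- function(polymer, config = sim_config(), duration,
                         smc = NULL, replicate = 1, stream = 0,
                         sample_every = 0) {
  stopifnot(duration >= 0)
  if (duration == 0) {
    return(if (sample_every > 0) {
      list(polymer = polymer, samples = list(), times = numeric())
    } else {
      polymer
    })
  }
  nsteps <- round(duration / config$dt)
  res <- cpp_run_dynamics(
    polymer_positions(polymer), unclass(config_ff(config)),
    nsteps = nsteps, dt = config$dt, smc = smc_to_cpp(smc),
    field = field_to_cpp(config$field),
    temperature = config$temperature, friction = config$friction,
    seed = config$seed, replicate = replicate, stream = stream,
    sample_every = if (sample_every > 0) round(sample_every / config$dt) else 0,
    scheme = if (identical(config$integrator, "euler")) 1L else 0L
  )
  out <- polymer
  out$positions <- res$positions
  colnames(out$positions) <- c("x", "y", "z")
  if (sample_every > 0) {
    list(polymer = out, samples = res$samples, times = res$sample_times)
  } else {
    out
  }
}

#' Relax a freshly generated conformation
#'
#' Runs a short energy minimisation (steepest descent with backtracking,
#' displacement-capped) to remove residual close contacts from the chain
#' generator, followed by `duration` \eqn{\tau_B} of Brownian dynamics so
#' the conformation decorrelates from its initial state. After
#' equilibration at defaults the chain's bond-vector correlation decays
#' with the target persistence length and the mean bond length sits near
#' the FENE+WCA minimum (about 0.97 \eqn{\sigma}).
#'
#' @inheritParams run_dynamics
#' @param duration Equilibration time in \eqn{\tau_B}
#'   (default `config$equilibration_time`); 0 returns the input unchanged.
#' @param minimize Whether to run the initial descent (skipped when
#'   `duration == 0`).
#' @return The equilibrated `smc_polymer`.
#' @export
equilibrate <- function(polymer, config = sim_config(),
                        duration = config$equilibration_time,
                        replicate = 1, minimize = TRUE) {
  stopifnot(duration >= 0)
  if (duration == 0) return(polymer)
  if (minimize) {
    res <- cpp_minimize(polymer_positions(polymer),
                        unclass(config_ff(config)),
                        field = field_to_cpp(config$field),
                        max_steps = 100, max_disp = 0.05)
    polymer$positions <- res$positions
  }
  run_dynamics(polymer, config, duration, replicate = replicate, stream = 4)
}

#' Steepest-descent relaxation
#'
#' Noise-free, displacement-capped steepest descent with backtracking line
#' halving; the total energy is non-increasing along the returned sequence.
#'
#' @inheritParams run_dynamics
#' @param max_steps Maximum descent iterations.
#' @param max_disp Per-iteration displacement cap in \eqn{\sigma}.
#' @return A list: relaxed `polymer`, final `energy` and the monotone
#'   `energies` sequence.
#' @export
minimize_energy <- function(polymer, config = sim_config(), smc = NULL,
                            max_steps = 200, max_disp = 0.05) {
  res <- cpp_minimize(polymer_positions(polymer),
                      unclass(config_ff(config)), smc = smc_to_cpp(smc),
                      field = field_to_cpp(config$field),
                      max_steps = max_steps, max_disp = max_disp)
  out <- polymer
  out$positions <- res$positions
  colnames(out$positions) <- c("x", "y", "z")
  list(polymer = out, energy = res$energy, energies = res$energies)
}
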