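#' Load an SMC complex onto the chain
#'
#' Selects, uniformly at random among eligible pairs, two beads that are
#' proximate in 3D (separation < 4\eqn{\sigma}) yet at least 3 beads apart
#' along the chain, assigns anchor and head roles at random, and installs
#' the SMC bonds of the configured variant (anchor-head spring and, for
#' two-spring variants, the spring between their loop-side neighbours).
#' The anchor is immutable for the rest of the run; only the head moves.
#'
#' @param polymer An equilibrated [make_polymer()] object.
#' @param config An [sim_config()].
#' @param replicate Replicate id entering the loading RNG stream.
#' @return An object of class `smc_state`.
#' @export
load_smc <- function(polymer, config = sim_config(), replicate = 1) {
  pos <- polymer_positions(polymer)
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  idx <- which(d < 4, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  sep1d <- abs(idx[, 1] - idx[, 2])
  # eligible: 3D < 4 sigma and 1D separation >= 3 beads
  idx <- idx[sep1d >= 3, , drop = FALSE]
  if (nrow(idx) == 0) {
    abort("load_smc: no eligible bead pair (3D distance < 4 sigma and 1D separation >= 3)")
  }
  pick <- with_seed(derive_seed(config$seed, replicate, 1), {
    k <- sample.int(nrow(idx), 1)
    swap <- runif(1) < 0.5
    list(k = k, swap = swap)
  })
  pair <- idx[pick$k, ]
  anchor <- if (pick$swap) pair[2] else pair[1]
  head <- if (pick$swap) pair[1] else pair[2]
  new_smc_state(anchor, head, config)
}

new_smc_state <- function(anchor, head, config) {
  stopifnot(abs(anchor - head) >= 3)
  structure(
    list(anchor = as.integer(anchor), head = as.integer(head),
         variant = config$variant, gamma = config$gamma,
         shell = config$shell, jump_cap = config$jump_cap,
         cone_orientation = config$cone_orientation,
         attempt_interval = config$attempt_interval,
         initial_loop = as.integer(anchor - head)),
    class = "smc_state"
  )
}

#' Construct an SMC state at given bead indices
#'
#' Lower-level constructor used by fixtures and tests; [load_smc()] is the
#' stochastic loader.
#'
#' @param anchor,head 1-based bead indices, at least 3 apart.
#' @param config An [sim_config()] supplying variant, gamma, shell and cap.
#' @return An `smc_state`.
#' @export
smc_state <- function(anchor, head, config = sim_config()) {
  new_smc_state(anchor, head, config)
}

#' Switch the structural variant of an SMC state
#'
#' Reconfigures the bond/penalty set and the capture-region geometry:
#' the baseline `two_spring_asym` uses two springs with the cone apex at
#' the head; `one_spring` drops the loop-side spring; `barycentre_axis`
#' keeps two springs but moves the cone apex to the barycentre of the four
#' bonded beads; `dihedral_asym` uses one spring plus the asymmetric
#' torsion penalty; `dihedral_sym` uses two springs plus the symmetric
#' torsion penalty.
#'
#' @param smc An `smc_state`.
#' @param variant New variant tag.
#' @return The updated `smc_state`.
#' @export
apply_variant <- function(smc, variant) {
  variants <- c("two_spring_asym", "one_spring", "barycentre_axis",
                "dihedral_asym", "dihedral_sym")
  if (!variant %in% variants) {
    abort(paste0("apply_variant: unknown variant '", variant, "'"))
  }
  smc$variant <- variant
  smc
}

#' Beads eligible for capture
#'
#' Applies the full capture rule from the current conformation: a bead is a
#' candidate if (a) it lies within the cone of half-aperture
#' \eqn{\gamma/2} about the capture axis, (b) its distance from the cone
#' apex lies in the radial shell (1--4 \eqn{\sigma}, the hinge reach),
#' (c) it is within `jump_cap` beads of the head along the chain, (d) it is
#' at least 3 beads from the anchor, and (e) it is not the current head or
#' its loop-side neighbour. At \eqn{\gamma = 360^\circ} the angular
#' condition is vacuous and membership reduces to the radial shell plus the
#' 1D filters.
#'
#' @param polymer The current conformation.
#' @param smc An `smc_state`.
#' @return Integer vector of candidate bead indices (1-based), possibly
#'   empty. A spatially degenerate axis (anchor and head coincide) yields
#'   an empty set.
#' @export
find_candidates <- function(polymer, smc) {
  as.integer(cpp_find_candidates(polymer_positions(polymer),
                                 smc_to_cpp(smc)))
}

#' Attempt one capture step
#'
#' Runs the capture rule once on a frozen conformation: find the candidate
#' set, pick one bead uniformly at random (if any), and move the head
#' there. The rebonding is irreversible work extraction: the anchor-head
#' spring is stretched to the captured bead and subsequently relaxes under
#' the dynamics, pulling the new segment in; no move ever pushes a captured
#' segment back out. On failure (empty candidate set) the bonds are left
#' unchanged.
#'
#' @param polymer The current conformation.
#' @param smc An `smc_state`.
#' @param seed,replicate RNG inputs for the capture stream.
#' @return A list: `event` (one-row tibble: success, old_head, new_head,
#'   signed_step = change in oriented loop length \eqn{l = n_a - n_h},
#'   candidate_count) and the updated `smc`.
#' @export
attempt_step <- function(polymer, smc, seed = 1, replicate = 1) {
  res <- cpp_attempt_step(polymer_positions(polymer), smc_to_cpp(smc),
                          seed = seed, replicate = replicate)
  smc$head <- as.integer(res$new_head)
  list(
    event = tibble(
      success = res$success, old_head = res$old_head,
      new_head = res$new_head, signed_step = res$signed_step,
      candidate_count = res$candidate_count
    ),
    smc = smc
  )
}

#' Oriented loop length of an SMC state
#'
#' \eqn{l = n_a - n_h}; its magnitude is the extruded loop size in beads.
#'
#' @param smc An `smc_state`.
#' @return Integer.
#' @export
loop_length <- function(smc) smc$anchor - smc$head

# internal: kernel representation
smc_to_cpp <- function(smc) {
  if (is.null(smc)) return(NULL)
  list(anchor = smc$anchor, head = smc$head,
       variant_id = variant_id(smc$variant), gamma = smc$gamma,
       shell_min = smc$shell[1], shell_max = smc$shell[2],
       jump_cap = smc$jump_cap,
       cone_ge = !identical(smc$cone_orientation, "printed"))
}

#' @export
print.smc_state <- function(x, ...) {
  cat("<smc_state> anchor", x$anchor, "| head", x$head, "| l =",
      loop_length(x), "|", x$variant, "| gamma =", x$gamma, "deg\n")
  invisible(x)
}
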