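#' Deterministic test conformations with known capture outcomes
#'
#' Builds small chains whose candidate sets and step outcomes are known by
#' construction, for exercising the capture rule against an independent
#' brute-force scan:
#'
#' * `straight_chain`: `n` collinear beads at 1 \eqn{\sigma} spacing. On
#'   this chain the only loadable pairs are those exactly 3 beads apart
#'   (3 \eqn{\sigma} < 4 \eqn{\sigma}; 4 beads would already be at
#'   4 \eqn{\sigma}).
#' * `loop_with_known_candidates`: a 30-bead conformation carrying an SMC
#'   (anchor 10, head 13) where exactly beads 15 and 16 satisfy the
#'   capture rule at \eqn{\gamma = 60^\circ} (and beads 15--18 at
#'   \eqn{\gamma = 360^\circ}).
#' * `planar_hairpin`: a 30-bead hairpin with anchor 30 and head 23
#'   (loop l = +7) where exactly one bead is capturable at
#'   \eqn{\gamma = 60^\circ}: bead 27, four beads inside the loop
#'   (`side = "inside"`, signed step -4), or bead 19, four beads outside
#'   (`side = "outside"`, signed step +4).
#' * `random_walk_chain`: a seeded [make_polymer()] random walk
#'   (reproducible across runs).
#'
#' @param name Fixture name.
#' @param n Bead count (straight/random chains).
#' @param seed Seed for `random_walk_chain`.
#' @param side For `planar_hairpin`: `"inside"` or `"outside"`.
#' @param config Optional [sim_config()] whose variant/cap settings are
#'   copied onto the fixture's SMC state (gamma is fixed by the fixture
#'   where expectations are attached).
#' @return A list of class `smc_fixture`: `polymer`, and where applicable
#'   `smc` (an `smc_state`), `expected_candidates` and
#'   `expected_signed_step`.
#' @examples
#' fx <- make_fixture("loop_with_known_candidates")
#' find_candidates(fx$polymer, fx$smc)   # 15, 16
#' @export
make_fixture <- function(name = c("straight_chain", "planar_hairpin",
                                  "loop_with_known_candidates",
                                  "random_walk_chain"),
                         n = 50, seed = 1,
                         side = c("inside", "outside"), config = NULL) {
  name <- match.arg(name)
  side <- match.arg(side)
  out <- switch(
    name,
    straight_chain = list(polymer = make_polymer(n, "straight")),
    random_walk_chain = list(polymer = make_polymer(n, "random_walk",
                                                    seed = seed)),
    loop_with_known_candidates = fixture_known_loop(config),
    planar_hairpin = fixture_hairpin(side, config)
  )
  structure(c(out, list(name = name)), class = "smc_fixture")
}

fixture_cfg <- function(config, gamma) {
  if (is.null(config)) {
    config <- desk_config(n_beads = 30, gamma = gamma, replicates = 2,
                          run_time = 100)
  } else {
    config$gamma <- gamma
  }
  config
}

# 30 beads; anchor 10, head 13 (l = -3); cone apex at bead 13 with axis +z.
# Beads 14-18 are the only 1D-eligible candidates; 14 sits under the inner
# shell radius, 17 and 18 outside the 30-degree half-aperture, so exactly
# {15, 16} are capturable at gamma = 60 (and {15, 16, 17, 18} at 360).
fixture_known_loop <- function(config) {
  pos <- matrix(0, 30, 3)
  for (j in 1:10) pos[j, ] <- c(0, 0, j - 10)
  pos[11, ] <- c(0.6, 0.6, 0.3)
  pos[12, ] <- c(0.6, 0.6, 1.3)
  pos[13, ] <- c(0, 0, 1.5)
  pos[14, ] <- c(0.9, 0, 1.7)
  pos[15, ] <- c(0.5, 0, 2.6)
  pos[16, ] <- c(0.3, 0, 3.5)
  pos[17, ] <- c(1.3, 0, 3.55)
  pos[18, ] <- c(2.3, 0, 3.6)
  for (j in 19:30) pos[j, ] <- c(2.3 + (j - 18), 0, 3.6)
  cfg <- fixture_cfg(config, gamma = 60)
  list(polymer = new_polymer(pos),
       smc = smc_state(anchor = 10, head = 13, cfg),
       expected_candidates = c(15L, 16L),
       expected_candidates_isotropic = c(15L, 16L, 17L, 18L))
}

# 30-bead hairpin; anchor 30 at (0,-1,0), head 23 at the origin, so the
# capture axis is +y with apex at the head. Exactly one bead passes the
# gamma = 60 rule: bead 27 (inside the loop, step -4) or bead 19 (outside,
# step +4), depending on `side`.
fixture_hairpin <- function(side, config) {
  pos <- matrix(0, 30, 3)
  pos[23, ] <- c(0, 0, 0)
  pos[30, ] <- c(0, -1, 0)
  if (side == "inside") {
    # inside arm carries the candidate at bead 27
    pos[24, ] <- c(-0.9, 0.3, 0)
    pos[25, ] <- c(-1.5, 1.0, 0)
    pos[26, ] <- c(-1.25, 1.9, 0)
    pos[27, ] <- c(0, 2.0, 0)
    pos[28, ] <- c(0, 0.83, 0.8)
    pos[29, ] <- c(0, -0.2, 0.8)
    # outside arm kept clear of the cone, running off at a shallow angle
    pos[22, ] <- c(1.1, 0.3, 0)
    pos[21, ] <- c(2.05, 0.6, 0)
    pos[20, ] <- c(3.0, 0.9, 0)
    pos[19, ] <- c(3.95, 1.2, 0)
    pos[18, ] <- c(4.9, 1.5, 0)
    for (j in 17:1) pos[j, ] <- c(4.9 + (18 - j) * 0.95, 1.5, 0)
    expected <- 27L
    step <- -4L
  } else {
    # inside arm detours through z, staying outside the cone
    pos[24, ] <- c(-0.9, 0.3, 0)
    pos[25, ] <- c(-0.9, 0.9, 0.9)
    pos[26, ] <- c(-0.6, 1.6, 1.3)
    pos[27, ] <- c(-0.2, 1.9, 1.9)
    pos[28, ] <- c(-0.1, 1.2, 1.3)
    pos[29, ] <- c(0, -0.1, 0.8)
    # outside arm carries the candidate at bead 19
    pos[22, ] <- c(1.1, 0.3, 0)
    pos[21, ] <- c(1.35, 1.25, 0)
    pos[20, ] <- c(1.45, 2.2, 0)
    pos[19, ] <- c(0.2, 2.35, 0)
    pos[18, ] <- c(1.6, 2.55, 0)
    for (j in 17:1) pos[j, ] <- c(1.6 + (18 - j) * 0.95, 2.85, 0)
    expected <- 19L
    step <- 4L
  }
  cfg <- fixture_cfg(config, gamma = 60)
  list(polymer = new_polymer(pos),
       smc = smc_state(anchor = 30, head = 23, cfg),
       expected_candidates = expected,
       expected_signed_step = step)
}

#' @export
print.smc_fixture <- function(x, ...) {
  cat("<smc_fixture>", x$name, "-", x$polymer$n_beads, "beads\n")
  invisible(x)
}
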