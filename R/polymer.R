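#' Create a bead-spring DNA polymer
#'
#' Builds a linear chain of `n_beads` beads of diameter \eqn{\sigma}
#' (10 nm, 30 bp each at the default mapping). The default study chain of
#' 400 beads therefore represents about 12 kbp (contour length about
#' 4 um). Two conformation generators are available:
#'
#' * `"random_walk"`: bond directions sampled from the Boltzmann weight of
#'   the Kratky-Porod bending term (so the chain starts with the target
#'   persistence-length statistics), with local self-avoidance enforced by
#'   rejection. This starting state still needs a short [equilibrate()]
#'   before production use.
#' * `"straight"`: a fully extended chain along x, mostly useful as a
#'   deterministic fixture.
#'
#' @param n_beads Number of beads (default 400).
#' @param conformation `"random_walk"` or `"straight"`.
#' @param seed Integer seed for the random-walk generator (deterministic:
#'   same seed, same chain).
#' @param persistence_length Persistence length in \eqn{\sigma} (default 5,
#'   i.e. 50 nm).
#' @param bond_length Initial bond spacing in \eqn{\sigma}.
#' @param min_dist Minimum distance allowed between non-bonded beads during
#'   generation (rejection threshold).
#' @return An object of class `smc_polymer`: a list with `positions`
#'   (n-by-3 matrix, \eqn{\sigma} units), `n_beads`, `persistence_length`
#'   and `bond_length`.
#' @examples
#' pol <- make_polymer(50, "random_walk", seed = 7)
#' summary(bond_lengths(pol))
#' @export
make_polymer <- function(n_beads = 400,
                         conformation = c("random_walk", "straight"),
                         seed = 1, persistence_length = 5,
                         bond_length = 1, min_dist = 0.9) {
  conformation <- match.arg(conformation)
  stopifnot(n_beads >= 2, persistence_length > 0, bond_length > 0)
  if (conformation == "straight") {
    pos <- cbind((seq_len(n_beads) - 1) * bond_length, 0, 0)
  } else {
    pos <- with_seed(seed, kp_walk(n_beads, persistence_length,
                                   bond_length, min_dist))
  }
  new_polymer(pos, persistence_length, bond_length)
}

new_polymer <- function(positions, persistence_length = 5, bond_length = 1) {
  positions <- as.matrix(positions)
  colnames(positions) <- c("x", "y", "z")
  p <- structure(
    list(positions = positions, n_beads = nrow(positions),
         persistence_length = persistence_length,
         bond_length = bond_length),
    class = "smc_polymer"
  )
  validate_polymer(p)
  p
}

# Kratky-Porod-distributed walk: cos(theta) at each joint follows
# exp(kp * cos(theta)) so local stiffness matches l_p from the start.
kp_walk <- function(n, lp, b, min_dist) {
  kp <- lp  # prefactor k_BT l_p / sigma with sigma = 1
  pos <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    ok <- FALSE
    best <- NULL
    best_d <- -Inf
    for (try in 1:80) {
      if (i == 2) {
        nd <- dir
      } else {
        u <- runif(1)
        cos_t <- 1 + log(u + (1 - u) * exp(-2 * kp)) / kp
        sin_t <- sqrt(max(0, 1 - cos_t^2))
        phi <- runif(1, 0, 2 * pi)
        basis <- ortho_basis(dir)
        nd <- cos_t * dir +
          sin_t * (cos(phi) * basis[[1]] + sin(phi) * basis[[2]])
        nd <- nd / sqrt(sum(nd^2))
      }
      cand <- pos[i - 1, ] + b * nd
      if (i <= 3) {
        d <- Inf
      } else {
        prev <- pos[seq_len(i - 2), , drop = FALSE]
        d <- sqrt(min(rowSums((prev - matrix(cand, nrow(prev), 3,
                                             byrow = TRUE))^2)))
      }
      if (d >= min_dist) {
        ok <- TRUE
        best <- list(nd = nd, cand = cand)
        break
      }
      if (d > best_d) {
        best_d <- d
        best <- list(nd = nd, cand = cand)
      }
    }
    pos[i, ] <- best$cand
    dir <- best$nd
    if (!ok && i == 2) dir <- c(1, 0, 0)
  }
  pos
}

ortho_basis <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- crossprod3(v, a)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- crossprod3(v, e1)
  e2 <- e2 / sqrt(sum(e2^2))
  list(e1, e2)
}

validate_polymer <- function(p) {
  if (!all(is.finite(p$positions))) {
    abort("polymer: non-finite coordinates")
  }
  # every backbone bond must sit strictly below the FENE divergence
  if (any(bond_lengths(p) >= 1.5)) {
    abort("polymer: backbone bond at or beyond R0 = 1.5 sigma")
  }
  invisible(p)
}

#' Backbone bond lengths of a polymer
#' @param polymer An `smc_polymer` (or n-by-3 matrix).
#' @return Numeric vector of the n-1 bond lengths in \eqn{\sigma}.
#' @export
bond_lengths <- function(polymer) {
  pos <- polymer_positions(polymer)
  d <- diff(pos)
  sqrt(rowSums(d^2))
}

#' Contour length of a polymer
#' @inheritParams bond_lengths
#' @param units A [unit_system()]; used for the nm value.
#' @return A named list with the contour length in \eqn{\sigma} and nm.
#' @export
contour_length <- function(polymer, units = unit_system()) {
  s <- sum(bond_lengths(polymer))
  list(sigma = s, nm = s * units$sigma_nm)
}

#' Bond-angle decay and fitted persistence length
#'
#' Computes the mean bond-vector correlation \eqn{\langle\cos\theta(s)\rangle}
#' as a function of contour separation `s` (in beads) over one or more
#' conformations, and fits the exponential decay
#' \eqn{\exp(-s\,\sigma/l_p)} to recover the persistence length.
#'
#' @param conformations A list of n-by-3 matrices (or `smc_polymer`s), or a
#'   single one.
#' @param max_s Largest contour separation used in the fit.
#' @return A list: `decay` tibble (s, mean_cos) and `lp` (fitted persistence
#'   length in \eqn{\sigma}).
#' @export
persistence_length_fit <- function(conformations, max_s = 12) {
  if (!is.list(conformations) || is.matrix(conformations)) {
    conformations <- list(conformations)
  }
  acc <- NULL
  for (cf in conformations) {
    pos <- polymer_positions(cf)
    b <- diff(pos)
    b <- b / sqrt(rowSums(b^2))
    nb <- nrow(b)
    cors <- vapply(seq_len(min(max_s, nb - 1)), function(s) {
      mean(rowSums(b[seq_len(nb - s), , drop = FALSE] *
                     b[seq_len(nb - s) + s, , drop = FALSE]))
    }, numeric(1))
    acc <- rbind(acc, cors)
  }
  mean_cos <- colMeans(acc)
  s <- seq_along(mean_cos)
  keep <- mean_cos > 0
  fit <- lm(log(mean_cos[keep]) ~ 0 + s[keep])
  list(decay = tibble(s = s, mean_cos = mean_cos),
       lp = -1 / unname(coef(fit)[1]))
}

#' @export
print.smc_polymer <- function(x, ...) {
  cat("<smc_polymer> ", x$n_beads, " beads, l_p = ",
      x$persistence_length, " sigma, contour ~ ",
      round(contour_length(x)$nm / 1000, 2), " um\n", sep = "")
  invisible(x)
}

#' Positions of a polymer as a tidy tibble
#' @param polymer An `smc_polymer`.
#' @return A tibble with columns bead, x, y, z.
#' @export
polymer_tbl <- function(polymer) {
  pos <- polymer_positions(polymer)
  tibble(bead = seq_len(nrow(pos)), x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

# accept either an smc_polymer or a bare matrix
polymer_positions <- function(polymer) {
  if (inherits(polymer, "smc_polymer")) {
    return(polymer$positions)
  }
  if (is.matrix(polymer) && ncol(polymer) == 3) {
    return(polymer)
  }
  abort("expected an smc_polymer or an n-by-3 coordinate matrix")
}
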