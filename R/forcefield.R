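#' Force-field parameters
#'
#' Collects every interaction constant of the model, in reduced units.
#' Defaults are the study values: WCA excluded volume with
#' \eqn{\epsilon = k_BT} and cutoff \eqn{2^{1/6}\sigma}; FENE backbone bonds
#' with \eqn{k = 30\,\epsilon/\sigma^2} and \eqn{R_0 = 1.5\sigma};
#' Kratky-Porod bending with prefactor \eqn{k_BT l_p/\sigma = 5\epsilon}
#' (persistence length 5 beads = 50 nm); SMC harmonic springs with
#' \eqn{k = 5\,\epsilon/\sigma^2} and rest length \eqn{r_0 = 1.6\sigma};
#' and a quadratic dihedral prefactor of \eqn{5\epsilon} for the torsion
#' variants.
#'
#' @param wca_epsilon,wca_sigma WCA energy and length scales.
#' @param fene_k,fene_R0 FENE spring constant and maximum extension.
#' @param kp_prefactor Bending prefactor \eqn{k_BT l_p/\sigma}.
#' @param smc_k,smc_r0 SMC harmonic spring constant and rest length.
#'   `smc_k` is deliberately weak (kleisin is disordered); the loop-growth
#'   statistics are insensitive to it over 2--8 \eqn{\epsilon/\sigma^2}.
#' @param quad_prefactor Quadratic dihedral coefficient for the torsion
#'   variants.
#' @return An object of class `smc_ff_params`.
#' @export
ff_params <- function(wca_epsilon = 1, wca_sigma = 1,
                      fene_k = 30, fene_R0 = 1.5,
                      kp_prefactor = 5,
                      smc_k = 5, smc_r0 = 1.6,
                      quad_prefactor = 5) {
  p <- list(wca_epsilon = wca_epsilon, wca_sigma = wca_sigma,
            wca_cutoff = 2^(1 / 6) * wca_sigma,
            fene_k = fene_k, fene_R0 = fene_R0,
            kp_prefactor = kp_prefactor,
            smc_k = smc_k, smc_r0 = smc_r0,
            quad_prefactor = quad_prefactor)
  bad <- names(p)[!vapply(p, function(v) is.numeric(v) && v > 0, logical(1))]
  if (length(bad)) {
    abort(paste0("ff_params: all constants must be strictly positive; bad: ",
                 paste(bad, collapse = ", ")))
  }
  if (fene_R0 <= wca_sigma) {
    abort("ff_params: fene_R0 must exceed wca_sigma")
  }
  structure(p, class = "smc_ff_params")
}

#' Pairwise and angular potentials of the model
#'
#' Closed-form energies, vectorised over their first argument. These are the
#' reference implementations used throughout the documentation and tests; the
#' integrator evaluates the same expressions in compiled code.
#'
#' `wca_energy()` is the purely repulsive truncated-shifted Lennard-Jones
#' (Weeks-Chandler-Andersen) excluded-volume term:
#' \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r \le 2^{1/6}\sigma}, zero beyond.
#'
#' `fene_energy()` adds the finitely extensible backbone spring
#' \eqn{-0.5 k R_0^2 \ln[1 - (r/R_0)^2]} to the WCA part; it diverges as
#' \eqn{r \to R_0}.
#'
#' `kratky_porod_energy()` is the bending penalty
#' \eqn{(k_BT l_p/\sigma)(1 - \cos\theta)} on a triplet of consecutive
#' beads, with \eqn{\theta = 0} for a straight (collinear) triplet.
#'
#' `harmonic_energy()` is the SMC spring \eqn{k (r - r_0)^2}.
#'
#' @param r Separation(s) in \eqn{\sigma}.
#' @param theta Bending angle(s) in radians, deviation from collinearity.
#' @param params An [ff_params()] object.
#' @return Energy in \eqn{\epsilon} (\eqn{k_BT}).
#' @examples
#' p <- ff_params()
#' wca_energy(1, p)          # exactly epsilon
#' wca_energy(2^(1 / 6), p)  # zero at the cutoff
#' kratky_porod_energy(pi / 2, p)
#' @export
wca_energy <- function(r, params = ff_params()) {
  if (any(r <= 0)) abort("wca_energy: separation must be positive")
  eps <- params$wca_epsilon
  sig <- params$wca_sigma
  sr6 <- (sig / r)^6
  ifelse(r <= params$wca_cutoff, 4 * eps * (sr6^2 - sr6) + eps, 0)
}

#' @rdname wca_energy
#' @export
fene_energy <- function(r, params = ff_params()) {
  if (any(r <= 0)) abort("fene_energy: separation must be positive")
  R0 <- params$fene_R0
  if (any(r >= R0)) {
    abort(paste0("fene_energy: bond overstretched (r >= R0 = ", R0,
                 " sigma); the FENE potential diverges there"))
  }
  wca_energy(r, params) -
    0.5 * params$fene_k * R0^2 * log(1 - (r / R0)^2)
}

#' @rdname wca_energy
#' @export
kratky_porod_energy <- function(theta, params = ff_params()) {
  if (any(theta < 0 | theta > pi)) {
    abort("kratky_porod_energy: theta must lie in [0, pi]")
  }
  params$kp_prefactor * (1 - cos(theta))
}

#' @rdname wca_energy
#' @export
harmonic_energy <- function(r, params = ff_params()) {
  if (any(r < 0)) abort("harmonic_energy: separation must be non-negative")
  params$smc_k * (r - params$smc_r0)^2
}

#' Angular energy of the torsion-constrained SMC variants
#'
#' The torsion variants replace (asymmetric) or supplement (symmetric) the
#' SMC springs with angular penalties on the DNA segments bonded at the
#' anchor and head. With capture axis \eqn{u} (anchor to head, normalised),
#' each bonded segment vector \eqn{b} pays a bending-type penalty
#' \eqn{(k_BT l_p/\sigma)(1 - \cos\delta)} where \eqn{\delta} is its
#' deviation from orthogonality to \eqn{u}, and each segment pair pays a
#' quadratic dihedral penalty \eqn{5\epsilon\,\varphi^2} on the angle
#' \eqn{\varphi} between their projections on the plane orthogonal to
#' \eqn{u}. The asymmetric form uses the two loop-side segments
#' (\eqn{\delta_1, \delta_2, \varphi_1}); the symmetric form additionally
#' uses the two outward segments (\eqn{\delta_3, \delta_4, \varphi_2}), so
#' it favours conformations in which all four boundary segments are
#' orthogonal to the capture axis.
#'
#' @param coords A named list of 3-vectors: `anchor`, `head`, `a_in`, `h_in`
#'   (positions of the anchor, head and their loop-side neighbours) and, for
#'   the symmetric variant, `a_out`, `h_out`.
#' @param variant `"asymmetric"` or `"symmetric"`.
#' @param params An [ff_params()] object.
#' @return A named list: the individual `delta` (radians), `phi` (radians)
#'   and the total `energy` in \eqn{\epsilon}.
#' @export
dihedral_energies <- function(coords, variant = c("asymmetric", "symmetric"),
                              params = ff_params()) {
  variant <- match.arg(variant)
  need <- c("anchor", "head", "a_in", "h_in")
  if (variant == "symmetric") need <- c(need, "a_out", "h_out")
  missing <- setdiff(need, names(coords))
  if (length(missing)) {
    abort(paste0("dihedral_energies: coords lacks ",
                 paste(missing, collapse = ", ")))
  }
  u <- coords$head - coords$anchor
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) abort("dihedral_energies: degenerate axis (anchor == head)")
  u <- u / nu

  seg_delta <- function(b) {
    nb <- sqrt(sum(b^2))
    if (nb < 1e-12) abort("dihedral_energies: degenerate segment")
    # signed deviation from orthogonality to the axis
    acos(max(-1, min(1, sum(b * u) / nb))) - pi / 2
  }
  u_orth <- function(b) {
    nb <- sqrt(sum(b^2))
    sint <- min(1, sqrt(sum(crossprod3(b, u)^2)) / nb)
    params$kp_prefactor * (1 - sint)
  }
  proj <- function(b) b - sum(b * u) * u
  phi_of <- function(b1, b2) {
    p1 <- proj(b1)
    p2 <- proj(b2)
    if (sqrt(sum(p1^2)) < 1e-9 || sqrt(sum(p2^2)) < 1e-9) {
      abort("dihedral_energies: undefined dihedral (segment parallel to axis)")
    }
    atan2(sum(u * crossprod3(p1, p2)), sum(p1 * p2))
  }

  b_a <- coords$a_in - coords$anchor
  b_h <- coords$h_in - coords$head
  delta <- c(seg_delta(b_a), seg_delta(b_h))
  phi <- phi_of(b_h, b_a)
  energy <- u_orth(b_a) + u_orth(b_h) + params$quad_prefactor * phi^2
  if (variant == "symmetric") {
    b_ao <- coords$a_out - coords$anchor
    b_ho <- coords$h_out - coords$head
    delta <- c(delta, seg_delta(b_ao), seg_delta(b_ho))
    phi <- c(phi, phi_of(b_ho, b_ao))
    energy <- energy + u_orth(b_ao) + u_orth(b_ho) +
      params$quad_prefactor * phi[2]^2
  }
  list(delta = delta, phi = phi, energy = energy)
}

# 3-vector cross product
crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Total energy and forces of a conformation
#'
#' Evaluates every energy term (and, for `total_forces()`, the analytic
#' minus-gradient) on a full conformation, including the SMC springs or
#' torsion terms when an SMC state is supplied and wall/tether contributions
#' when an external field is supplied.
#'
#' @param polymer An [make_polymer()] object (or a bare n-by-3 matrix).
#' @param smc Optional [load_smc()] state.
#' @param params An [ff_params()] object.
#' @param field Optional [external_field()].
#' @return `total_energy()`: a named vector of energy terms (in
#'   \eqn{\epsilon}) with a `total`; `total_forces()`: an n-by-3 matrix of
#'   forces in \eqn{\epsilon/\sigma}.
#' @export
total_energy <- function(polymer, smc = NULL, params = ff_params(),
                         field = NULL) {
  pos <- polymer_positions(polymer)
  cpp_energy_terms(pos, unclass(params), smc_to_cpp(smc), field_to_cpp(field))
}

#' @rdname total_energy
#' @export
total_forces <- function(polymer, smc = NULL, params = ff_params(),
                         field = NULL) {
  pos <- polymer_positions(polymer)
  cpp_total_forces(pos, unclass(params), smc_to_cpp(smc), field_to_cpp(field))
}
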