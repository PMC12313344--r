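p <- ff_params()

test_that("WCA potential matches its closed form and cutoff behaviour", {
  expect_equal(wca_energy(2^(1 / 6), p), 0, tolerance = 1e-12)
  expect_equal(wca_energy(1, p), 1)           # 4eps(1-1) + eps
  expect_equal(wca_energy(3, p), 0)
  # continuity at the cutoff
  expect_lt(wca_energy(2^(1 / 6) - 1e-8, p), 1e-6)
  expect_error(wca_energy(0, p), "positive")
  expect_error(wca_energy(-1, p), "positive")
})

test_that("FENE bond diverges at R0 and has its minimum near one bead", {
  # closed form at the WCA cutoff (WCA part exactly zero there)
  r <- 2^(1 / 6)
  expect_equal(fene_energy(r, p),
               -0.5 * 30 * 1.5^2 * log(1 - (r / 1.5)^2),
               tolerance = 1e-12)
  # monotone divergence approaching R0
  rs <- seq(1.40, 1.4999, length.out = 50)
  expect_true(all(diff(fene_energy(rs, p)) > 0))
  expect_gt(fene_energy(1.4999, p), 100)
  expect_error(fene_energy(1.5, p), "overstretch")
  # 1-D numerical minimisation oracle: minimiser in (0.9, 1.1) sigma
  opt <- optimize(fene_energy, c(0.5, 1.49), params = p)
  expect_gt(opt$minimum, 0.9)
  expect_lt(opt$minimum, 1.1)
})

test_that("Kratky-Porod and harmonic terms match closed forms", {
  expect_equal(kratky_porod_energy(0, p), 0)
  expect_equal(kratky_porod_energy(pi / 2, p), 5)
  expect_equal(kratky_porod_energy(pi, p), 10)
  expect_error(kratky_porod_energy(-0.1, p), "theta")
  expect_equal(harmonic_energy(1.6, p), 0)
  expect_equal(harmonic_energy(2.6, p), 5)    # k * 1^2
  expect_equal(harmonic_energy(0.6, p), 5)    # symmetric about r0
})

test_that("dihedral-variant energies: minima, quadratic term, additivity", {
  # all segments orthogonal to the axis, parallel projections: zero energy
  co <- list(anchor = c(0, 0, 0), head = c(0, 0, 2),
             a_in = c(1, 0, 0), h_in = c(1, 0, 2),
             a_out = c(1, 0, 0.01), h_out = c(1, 0, 1.99))
  asym <- dihedral_energies(co, "asymmetric", p)
  expect_equal(asym$energy, 0, tolerance = 1e-10)
  # phi = 1 rad with orthogonal segments: quadratic term alone = 5 eps
  co2 <- co
  co2$h_in <- c(cos(1), sin(1), 2)
  asym2 <- dihedral_energies(co2, "asymmetric", p)
  expect_equal(abs(asym2$phi[1]), 1, tolerance = 1e-10)
  expect_equal(asym2$energy, 5, tolerance = 1e-10)
  # symmetric = asymmetric + the extra delta3, delta4, phi2 terms
  sym <- dihedral_energies(co2, "symmetric", p)
  extra <- kratky_porod_energy(abs(dihedral_energies(co2, "symmetric", p)$delta[3]), p) +
    kratky_porod_energy(abs(sym$delta[4]), p) + 5 * sym$phi[2]^2
  expect_equal(sym$energy, asym2$energy + extra, tolerance = 1e-10)
  # degenerate axis rejected
  co3 <- co
  co3$head <- co3$anchor
  expect_error(dihedral_energies(co3, "asymmetric", p), "degenerate")
  # segment parallel to the axis: undefined dihedral frame
  co4 <- co
  co4$a_in <- c(0, 0, 1)
  expect_error(dihedral_energies(co4, "asymmetric", p), "dihedral")
})

test_that("kernel energies agree with the R reference term by term", {
  pol <- test_chain(40, seed = 11, duration = 100)
  pos <- pol$positions
  # backbone terms against direct R sums
  bl <- bond_lengths(pol)
  fene_ref <- sum(fene_energy(bl, p))
  b <- diff(pos)
  bn <- b / sqrt(rowSums(b^2))
  cosang <- rowSums(bn[-nrow(bn), , drop = FALSE] * bn[-1, , drop = FALSE])
  bend_ref <- sum(p$kp_prefactor * (1 - cosang))
  d <- as.matrix(dist(pos))
  wca_ref <- 0
  for (i in seq_len(nrow(pos) - 2)) {
    for (j in (i + 2):nrow(pos)) {
      wca_ref <- wca_ref + wca_energy(d[i, j], p)
    }
  }
  terms <- total_energy(pol)
  expect_equal(terms[["fene"]], fene_ref, tolerance = 1e-10)
  expect_equal(terms[["bend"]], bend_ref, tolerance = 1e-10)
  expect_equal(terms[["wca"]], wca_ref, tolerance = 1e-10)

  # SMC terms: springs and the torsion bundle against the R reference
  cfg <- desk_config(n_beads = 40, replicates = 2, variant = "dihedral_asym")
  smc <- smc_state(anchor = 8, head = 20, cfg)
  terms2 <- total_energy(pol, smc)
  expect_equal(terms2[["smc_spring"]],
               harmonic_energy(d[8, 20], p), tolerance = 1e-10)
  co <- list(anchor = pos[8, ], head = pos[20, ],
             a_in = pos[9, ], h_in = pos[19, ])
  expect_equal(terms2[["smc_angular"]],
               dihedral_energies(co, "asymmetric", p)$energy,
               tolerance = 1e-8)
  # symmetric variant adds the outward-segment terms
  smc4 <- apply_variant(smc, "dihedral_sym")
  co4 <- c(co, list(a_out = pos[7, ], h_out = pos[21, ]))
  terms4 <- total_energy(pol, smc4)
  expect_equal(terms4[["smc_angular"]],
               dihedral_energies(co4, "symmetric", p)$energy,
               tolerance = 1e-8)
})

test_that("analytic forces match central-difference gradients for every variant", {
  pol <- test_chain(20, seed = 7, duration = 100)
  cfg <- desk_config(n_beads = 20, replicates = 2)
  smc0 <- smc_state(anchor = 3, head = 12, cfg)
  h <- 1e-6
  for (v in c("two_spring_asym", "one_spring", "barycentre_axis",
              "dihedral_asym", "dihedral_sym")) {
    smc <- apply_variant(smc0, v)
    F <- total_forces(pol, smc)
    pos <- pol$positions
    for (i in c(2, 3, 4, 11, 12, 13)) {
      for (k in 1:3) {
        pp <- pos; pp[i, k] <- pp[i, k] + h
        pm <- pos; pm[i, k] <- pm[i, k] - h
        fd <- -(total_energy(pp, smc)[["total"]] -
                  total_energy(pm, smc)[["total"]]) / (2 * h)
        expect_equal(F[i, k], fd, tolerance = 1e-4,
                     label = sprintf("force[%d,%d] (%s)", i, k, v))
      }
    }
    # no external field: total force sums to zero (the torsion bundle uses
    # finite-difference gradients, hence the looser bound)
    expect_lt(max(abs(colSums(F))), 1e-5)
  }
})

test_that("interior beads of a straight relaxed chain feel ~zero net force; close pairs repel", {
  # straight chain with bonds at the FENE+WCA minimum
  r_min <- optimize(fene_energy, c(0.5, 1.49), params = p)$minimum
  pos <- cbind((0:19) * r_min, 0, 0)
  F <- total_forces(pos)
  expect_lt(max(abs(F[2:19, ])), 1e-6)
  # two non-bonded beads inside the WCA cutoff (2^(1/6) sigma) repel along
  # their connecting line; beyond the cutoff the pair force vanishes
  # (backbone terms switched off so only the WCA pair acts)
  tri <- rbind(c(0, 0, 0), c(10, 0, 0), c(1.05, 0, 0))
  p_nb <- c(unclass(p), list(bonds_on = FALSE, bend_on = FALSE))
  Ft <- smcloop:::cpp_total_forces(tri, p_nb)
  expect_lt(Ft[1, 1], 0)   # pushed towards -x
  expect_gt(Ft[3, 1], 0)   # pushed towards +x
  expect_equal(Ft[1, 2:3], c(0, 0), tolerance = 1e-12)
  far <- rbind(c(0, 0, 0), c(10, 0, 0), c(1.2, 0, 0))
  expect_equal(max(abs(smcloop:::cpp_total_forces(far, p_nb))), 0)
})

test_that("ff_params rejects non-positive constants", {
  expect_error(ff_params(smc_k = 0), "positive")
  expect_error(ff_params(fene_R0 = 0.5), "exceed")
})
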