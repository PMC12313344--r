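test_that("a free bead diffuses with D = kT/xi = 1 sigma^2/tau_B", {
  # overdamped update on a single bead: mean squared increment over windows
  # of 1 tau_B must be 6 D t; pooled over replicates and windows
  p <- unclass(ff_params())
  msds <- numeric()
  for (rep in 1:40) {
    r <- smcloop:::cpp_run_dynamics(matrix(0, 1, 3), p, nsteps = 10000,
                                    dt = 5e-4, seed = 99, replicate = rep,
                                    sample_every = 2000, scheme = 1L)
    xs <- do.call(rbind, r$samples)          # positions every 1 tau_B
    inc <- diff(rbind(c(0, 0, 0), xs))
    msds <- c(msds, rowSums(inc^2))
  }
  expect_equal(mean(msds), 6, tolerance = 0.05)
})

test_that("the inertial integrator is diffusive on multi-tau_B scales", {
  p <- unclass(ff_params())
  msds <- numeric()
  for (rep in 1:30) {
    r <- smcloop:::cpp_run_dynamics(matrix(0, 1, 3), p, nsteps = 5000,
                                    dt = 0.01, seed = 17, replicate = rep,
                                    sample_every = 1000, scheme = 0L)
    xs <- do.call(rbind, r$samples)          # every 10 tau_B
    inc <- diff(rbind(c(0, 0, 0), xs))
    msds <- c(msds, rowSums(inc^2))
  }
  # 6 D t with the small inertial correction 6D(t - m/xi) at t = 10
  expect_equal(mean(msds), 6 * (10 - 1), tolerance = 0.08)
})

test_that("with all potentials off the centre of mass diffuses with D/n", {
  p <- c(unclass(ff_params()),
         list(wca_on = FALSE, bonds_on = FALSE, bend_on = FALSE))
  n <- 10
  msds <- numeric()
  for (rep in 1:40) {
    r <- smcloop:::cpp_run_dynamics(matrix(0, n, 3), p, nsteps = 4000,
                                    dt = 5e-4, seed = 31, replicate = rep,
                                    sample_every = 2000, scheme = 1L)
    coms <- t(vapply(r$samples, colMeans, numeric(3)))
    inc <- diff(rbind(c(0, 0, 0), coms))
    msds <- c(msds, rowSums(inc^2))
  }
  expect_equal(mean(msds), 6 / n, tolerance = 0.12)
})

test_that("steepest descent never increases the energy", {
  pol <- make_polymer(30, "random_walk", seed = 5)
  res <- minimize_energy(pol, desk_config(n_beads = 30, replicates = 2),
                         max_steps = 80)
  expect_true(all(diff(res$energies) <= 1e-9))
  expect_lt(res$energy, res$energies[1])
})

test_that("equilibrate with zero duration is the identity", {
  pol <- make_polymer(20, "straight")
  expect_identical(equilibrate(pol, duration = 0), pol)
  expect_identical(run_dynamics(pol, desk_config(n_beads = 20), 0), pol)
})

test_that("equilibrated chains keep bonds near the FENE+WCA minimum", {
  pol <- test_chain(60, seed = 4, duration = 300)
  m <- mean(bond_lengths(pol))
  expect_gt(m, 0.9)
  expect_lt(m, 1.1)
  expect_true(all(bond_lengths(pol) < 1.5))
})

test_that("trajectories are bitwise reproducible for identical seeds", {
  cfg <- desk_config(n_beads = 30, replicates = 2, seed = 12)
  pol <- make_polymer(30, "random_walk", seed = 2)
  a <- run_dynamics(pol, cfg, duration = 20, replicate = 1)
  b <- run_dynamics(pol, cfg, duration = 20, replicate = 1)
  c <- run_dynamics(pol, cfg, duration = 20, replicate = 2)
  expect_identical(a$positions, b$positions)
  expect_false(identical(a$positions, c$positions))
})

test_that("slab confinement keeps every bead inside the gap for the whole run", {
  cfg <- desk_config(n_beads = 40, replicates = 2,
                     field = external_field("slab", slab_gap = 3))
  pol <- make_polymer(40, "random_walk", seed = 8)
  pol$positions[, 3] <- pol$positions[, 3] * 0.05  # start inside the slab
  pol <- equilibrate(pol, cfg, duration = 20)      # resolve squashed contacts
  res <- run_dynamics(pol, cfg, duration = 100, sample_every = 5)
  zmax <- max(vapply(res$samples, function(m) max(abs(m[, 3])), numeric(1)))
  expect_lt(zmax, 1.5)  # within +/- gap/2
})

test_that("end tethering stretches the chain monotonically with force", {
  ext <- vapply(c(0, 0.5, 1), function(f) {
    cfg <- desk_config(
      n_beads = 40, replicates = 2, seed = 5,
      field = if (f > 0) external_field("tether", tether_force = f)
              else external_field("none"))
    exts <- vapply(1:6, function(rep) {
      pol <- make_polymer(40, "random_walk", seed = 100 + rep)
      pol <- equilibrate(pol, cfg, duration = 400, replicate = rep)
      abs(pol$positions[40, 1] - pol$positions[1, 1])
    }, numeric(1))
    mean(exts)
  }, numeric(1))
  expect_true(ext[1] < ext[2] && ext[2] < ext[3])
})

test_that("persistence length is recovered from equilibrated conformations", {
  cfg <- desk_config(n_beads = 80, replicates = 2, seed = 21)
  confs <- list()
  for (rep in 1:3) {
    pol <- make_polymer(80, "random_walk", seed = 300 + rep)
    pol <- equilibrate(pol, cfg, duration = 200, replicate = rep)
    res <- run_dynamics(pol, cfg, duration = 500, replicate = rep,
                        stream = 6, sample_every = 50)
    confs <- c(confs, res$samples)
  }
  fit <- persistence_length_fit(confs, max_s = 10)
  # the discrete bending chain with prefactor kp = 5 has bond-correlation
  # decay <cos theta> = coth(kp) - 1/kp = 0.8, i.e. l_p = -1/ln(0.8) ~ 4.5
  # sigma before excluded-volume swelling; dynamics must preserve that
  lp_theory <- -1 / log(1 / tanh(5) - 1 / 5)
  expect_gt(fit$lp, 0.85 * lp_theory)
  expect_lt(fit$lp, 1.25 * lp_theory)
})
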