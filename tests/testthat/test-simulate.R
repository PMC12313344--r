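cfg_tiny <- desk_config(n_beads = 50, run_time = 1000,
                        equilibration_time = 200, replicates = 2, seed = 3)

test_that("the extrusion pipeline runs, logs events and keeps its invariants", {
  sim <- simulate_extrusion(cfg_tiny)
  ev <- sim$events
  expect_equal(nrow(ev), 2 * 10)  # 2 replicates x 10 attempts
  expect_setequal(unique(ev$replicate), 1:2)
  # failed attempts change nothing
  fails <- dplyr::filter(ev, !success)
  expect_true(all(fails$old_head == fails$new_head))
  expect_true(all(fails$signed_step == 0))
  # jump cap and anchor-distance bookkeeping
  succ <- dplyr::filter(ev, success)
  expect_true(all(abs(succ$new_head - succ$old_head) <= cfg_tiny$jump_cap))
  expect_true(all(abs(succ$new_head - succ$anchor) >= 3))
  # head never touches the termini
  expect_true(all(ev$new_head >= 2 & ev$new_head <= 49))
  # trace is consistent with the event log: l = anchor - head
  tr <- dplyr::filter(sim$trace, replicate == 1)
  ev1 <- dplyr::filter(ev, replicate == 1)
  expect_equal(tr$loop_length[-1], ev1$anchor - ev1$new_head)
  # l changes only at attempts, by exactly the logged signed step
  expect_equal(diff(tr$loop_length), ev1$signed_step)
})

test_that("identical configurations reproduce the event log exactly", {
  a <- simulate_extrusion(cfg_tiny)
  b <- simulate_extrusion(cfg_tiny)
  expect_identical(a$events, b$events)
  expect_identical(a$trace, b$trace)
  # replicates are independent: different loading points or step sequences
  expect_false(identical(
    dplyr::filter(a$events, replicate == 1)$new_head,
    dplyr::filter(a$events, replicate == 2)$new_head
  ))
  # a different seed gives a different realisation
  cfg2 <- cfg_tiny
  cfg2$seed <- 99
  c <- simulate_extrusion(cfg2)
  expect_false(identical(a$events$new_head, c$events$new_head))
})

test_that("tidy/glance/autoplot methods work on simulation objects", {
  sim <- simulate_extrusion(cfg_tiny)
  expect_identical(tidy(sim), sim$events)
  g <- glance(sim)
  expect_true(g$success_probability >= 0 && g$success_probability <= 1)
  pl <- autoplot(sim)
  expect_s3_class(pl, "ggplot")
  expect_s3_class(plot_step_histogram(sim), "ggplot")
})

test_that("a widened jump cap is honoured end to end", {
  cfg <- cfg_tiny
  cfg$jump_cap <- 20
  sim <- simulate_extrusion(cfg)
  succ <- dplyr::filter(sim$events, success)
  expect_true(all(abs(succ$new_head - succ$old_head) <= 20))
  # histogram support in beads and nm respects the cap
  st <- step_statistics(sim)
  expect_true(all(abs(st$histogram$step) <= 20))
  expect_true(all(abs(st$histogram$step_nm) <= 200))
})

test_that("every structural variant runs through the full pipeline", {
  for (v in c("one_spring", "barycentre_axis", "dihedral_asym",
              "dihedral_sym")) {
    cfg <- cfg_tiny
    cfg$variant <- v
    sim <- simulate_extrusion(cfg, replicates = 1)
    expect_equal(unique(sim$events$variant), v)
    expect_equal(nrow(sim$events), 10)
  }
})

test_that("config validation lists offending keys", {
  expect_error(desk_config(gamma = 0), "gamma")
  expect_error(desk_config(gamma = 400), "gamma")
  expect_error(desk_config(dt = -1), "dt")
  expect_error(desk_config(dt = 0.02), "dt")
  expect_error(desk_config(integrator = "euler", dt = 0.01), "[Ee]uler")
  expect_error(desk_config(shell = c(4, 1)), "shell")
  expect_error(desk_config(n_beads = 4), "n_beads")
  err <- tryCatch(desk_config(gamma = -5, dt = 0), error = conditionMessage)
  expect_match(err, "gamma")
  expect_match(err, "dt")
})
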