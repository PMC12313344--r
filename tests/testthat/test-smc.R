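test_that("loading picks 3D-proximate pairs at least 3 beads apart", {
  cfg <- desk_config(n_beads = 50, replicates = 2)
  pol <- make_polymer(50, "straight")
  # on a fully extended chain only pairs exactly 3 beads apart are < 4 sigma
  for (rep in 1:20) {
    smc <- load_smc(pol, cfg, replicate = rep)
    expect_equal(abs(smc$anchor - smc$head), 3)
  }
})

test_that("loading is uniform over eligible pairs and role assignment is random", {
  # 5 collinear beads at 1 sigma spacing: strictly-closer-than-4-sigma plus
  # 1D separation >= 3 leaves exactly the pairs (1,4) and (2,5); the pair
  # (1,5) sits at exactly 4 sigma and is excluded by the strict inequality
  cfg <- desk_config(n_beads = 10, replicates = 2)
  pol <- make_polymer(5, "straight")
  picks <- vapply(1:3000, function(rep) {
    smc <- load_smc(pol, cfg, replicate = rep)
    paste(sort(c(smc$anchor, smc$head)), collapse = "-")
  }, character(1))
  tab <- table(picks)
  expect_setequal(names(tab), c("1-4", "2-5"))
  expect_true(all(abs(tab / 3000 - 1 / 2) < 0.05))
  # anchor/head assignment randomised
  anchors <- vapply(1:500, function(rep) {
    load_smc(pol, cfg, replicate = rep)$anchor
  }, integer(1))
  expect_gt(mean(anchors < 4), 0.35)
  expect_lt(mean(anchors < 4), 0.65)
})

test_that("loading fails cleanly when no pair is eligible", {
  cfg <- desk_config(n_beads = 10, replicates = 2)
  pos <- cbind((0:9) * 1.45, 0, 0)  # stretched: 3-bead separation is 4.35
  pol <- smcloop:::new_polymer(pos)
  expect_error(load_smc(pol, cfg), "no eligible")
})

test_that("capture geometry: on-axis in-shell beads pass, orthogonal ones fail", {
  # head (bead 4) at the origin, axis +z
  pos <- rbind(
    c(0, 0, -2), c(0, 0, -1.2), c(0, 0, -0.5), c(0, 0, 0),
    c(0, 0, 2),      # bead 5: on-axis at 2 sigma -> candidate at gamma = 60
    c(2, 0, 0.5),    # bead 6: nearly orthogonal -> only at gamma = 360
    c(0, 0, 30)      # bead 7: far outside the shell
  )
  cfg <- desk_config(n_beads = 10, gamma = 60, replicates = 2)
  smc <- smc_state(anchor = 1, head = 4, cfg)
  expect_equal(find_candidates(pos, smc), 5L)
  smc$gamma <- 360
  expect_equal(find_candidates(pos, smc), c(5L, 6L))
  # smc states closer than 3 beads are rejected outright
  expect_error(smc_state(anchor = 2, head = 4, cfg))
})

test_that("fixtures reproduce their analytically known candidate sets", {
  fx <- make_fixture("loop_with_known_candidates")
  expect_equal(find_candidates(fx$polymer, fx$smc), fx$expected_candidates)
  # isotropic limit: membership reduces to shell + 1D filters
  smc360 <- fx$smc
  smc360$gamma <- 360
  expect_equal(find_candidates(fx$polymer, smc360),
               fx$expected_candidates_isotropic)
  for (side in c("inside", "outside")) {
    hp <- make_fixture("planar_hairpin", side = side)
    expect_equal(find_candidates(hp$polymer, hp$smc),
                 hp$expected_candidates)
  }
})

test_that("candidate sets equal the brute-force oracle on every fixture and on random chains", {
  fx <- make_fixture("loop_with_known_candidates")
  for (g in c(30, 60, 120, 360)) {
    smc <- fx$smc
    smc$gamma <- g
    expect_equal(find_candidates(fx$polymer, smc),
                 brute_force_candidates(fx$polymer$positions, 10, 13, g))
  }
  pol <- test_chain(60, seed = 4, duration = 300)
  cfg <- desk_config(n_beads = 60, replicates = 2)
  set.seed(9)
  for (i in 1:25) {
    a <- sample(3:58, 1)
    h_off <- sample(c(-8:-3, 3:8), 1)
    h <- max(1, min(60, a + h_off))
    if (abs(a - h) < 3) next
    g <- sample(c(45, 90, 180, 270, 360), 1)
    v <- sample(c("two_spring_asym", "barycentre_axis"), 1)
    cfg$gamma <- g
    smc <- apply_variant(smc_state(a, h, cfg), v)
    expect_equal(find_candidates(pol, smc),
                 brute_force_candidates(pol$positions, a, h, g, variant = v),
                 label = sprintf("a=%d h=%d g=%d %s", a, h, g, v))
  }
})

test_that("candidate membership is invariant under rigid rotation", {
  fx <- make_fixture("loop_with_known_candidates")
  R <- random_rotation(3)
  rotated <- fx$polymer
  rotated$positions <- fx$polymer$positions %*% t(R)
  expect_equal(find_candidates(rotated, fx$smc), fx$expected_candidates)
})

test_that("the barycentre variant moves the cone apex", {
  # straight chain, anchor 10, head 13, axis +x. From the head the shell
  # reaches beads 14..17; from the barycentre (1.5 sigma behind the head)
  # it reaches only 14..15.
  pol <- make_polymer(30, "straight")
  cfg <- desk_config(n_beads = 30, gamma = 60, replicates = 2)
  smc <- smc_state(10, 13, cfg)
  expect_equal(find_candidates(pol, smc), c(14L, 15L, 16L, 17L))
  smcb <- apply_variant(smc, "barycentre_axis")
  expect_equal(find_candidates(pol, smcb), c(14L, 15L))
})

test_that("a degenerate capture axis yields an empty candidate set", {
  pos <- make_polymer(30, "straight")$positions
  pos[13, ] <- pos[10, ] + c(1e-12, 0, 0)  # head collapses onto the anchor
  cfg <- desk_config(n_beads = 30, replicates = 2)
  smc <- smc_state(10, 13, cfg)
  expect_length(find_candidates(pos, smc), 0)
  res <- attempt_step(pos, smc, seed = 1)
  expect_false(res$event$success)
})

test_that("attempt semantics: forced choice, sign bookkeeping, failed attempts", {
  for (side in c("inside", "outside")) {
    hp <- make_fixture("planar_hairpin", side = side)
    res <- attempt_step(hp$polymer, hp$smc, seed = 1)
    expect_true(res$event$success)
    expect_equal(res$event$new_head, hp$expected_candidates)
    expect_equal(res$event$signed_step, hp$expected_signed_step)
    expect_equal(res$smc$head, hp$expected_candidates)
    # anchor never changes
    expect_equal(res$smc$anchor, hp$smc$anchor)
  }
  # empty candidate set: bonds left unchanged
  fx <- make_fixture("loop_with_known_candidates")
  smc <- fx$smc
  smc$gamma <- 1
  res <- attempt_step(fx$polymer, smc, seed = 1)
  expect_false(res$event$success)
  expect_equal(res$event$old_head, res$event$new_head)
  expect_equal(res$event$signed_step, 0)
  expect_equal(res$event$candidate_count, 0)
})

test_that("printed-orientation audit switch inverts the cone", {
  fx <- make_fixture("loop_with_known_candidates")
  smc <- fx$smc
  smc$cone_orientation <- "printed"
  # the printed inequality keeps exactly the beads the forward cone drops
  got <- find_candidates(fx$polymer, smc)
  expect_equal(got, setdiff(fx$expected_candidates_isotropic,
                            fx$expected_candidates))
  # at gamma = 360 the printed form selects (essentially) nothing
  smc$gamma <- 360
  expect_length(find_candidates(fx$polymer, smc), 0)
})

test_that("apply_variant validates tags and find_candidates respects the jump cap", {
  cfg <- desk_config(n_beads = 30, replicates = 2)
  smc <- smc_state(10, 13, cfg)
  expect_error(apply_variant(smc, "nonsense"), "unknown variant")
  pol <- make_polymer(30, "straight")
  smc20 <- smc_state(10, 13, cfg)
  smc20$jump_cap <- 2
  expect_true(all(abs(find_candidates(pol, smc20) - 13) <= 2))
})
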