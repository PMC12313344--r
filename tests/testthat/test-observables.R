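mk_trace <- function(mat, dt = 100) {
  # mat: replicates in columns
  dplyr::bind_rows(lapply(seq_len(ncol(mat)), function(r) {
    tibble::tibble(replicate = r, time = (seq_len(nrow(mat)) - 1) * dt,
                   loop_length = mat[, r])
  }))
}

test_that("RMS extruded length: degenerate ensembles and sign insensitivity", {
  tr <- mk_trace(cbind(rep(7, 11), rep(7, 11)))
  expect_equal(rms_extruded_length(tr, boot = 0)$rms, rep(7, 11))
  tr2 <- mk_trace(cbind(rep(5, 6), rep(-5, 6)))
  expect_equal(rms_extruded_length(tr2, boot = 0)$rms, rep(5, 6))
  # mismatched grids are rejected
  bad <- dplyr::bind_rows(
    tibble::tibble(replicate = 1, time = c(0, 100), loop_length = 1),
    tibble::tibble(replicate = 2, time = c(0, 50), loop_length = 1)
  )
  expect_error(rms_extruded_length(bad), "time grid")
})

test_that("scaling-exponent fit recovers exact power laws", {
  t <- seq(100, 10000, by = 100)
  lin <- tibble::tibble(time = t, rms = t)
  expect_equal(fit_scaling_exponent(lin, c(100, 10000))$exponent, 1,
               tolerance = 1e-10)
  half <- tibble::tibble(time = t, rms = sqrt(t))
  expect_equal(fit_scaling_exponent(half, c(100, 10000))$exponent, 0.5,
               tolerance = 1e-10)
  expect_error(fit_scaling_exponent(tibble::tibble(time = t, rms = -t)),
               "non-positive")
  ft <- fit_scaling_exponent(half)
  expect_s3_class(glance(ft), "tbl_df")
  expect_equal(tidy(ft)$estimate[2], 0.5, tolerance = 1e-10)
})

test_that("a reflected random-walk ensemble scales as t^(1/2)", {
  tr <- reflected_walk_traces(100, 400, seed = 6)
  curve <- rms_extruded_length(tr, boot = 0)
  fit <- fit_scaling_exponent(curve)
  expect_equal(fit$exponent, 0.5, tolerance = 0.1)
  expect_lt(abs(fit$exponent - 0.5), 0.05 + 2 * fit$se)
})

test_that("step statistics follow the printed counting rules", {
  ev <- tibble::tibble(
    success = c(rep(TRUE, 6), rep(FALSE, 4)),
    abs_step = c(3, 3, -2, 1, 2, -1, 0, 0, 0, 0),
    anchor = 50
  )
  st <- step_statistics(ev)
  expect_equal(st$summary$success_probability, 0.6)
  expect_equal(st$summary$n_forward / st$summary$n_backward, 2)
  # s = sum(sign * S) / N over successful steps
  st2 <- step_statistics(tibble::tibble(
    success = rep(TRUE, 3), abs_step = c(3, 3, -2), anchor = 1))
  expect_equal(st2$summary$mean_step, 4 / 3)
  expect_equal(st2$summary$mean_step_nm, 40 / 3)
  # histogram normalises and is tidy-accessible
  expect_equal(sum(tidy(st)$prob), 1)
  expect_equal(glance(st), st$summary)
})

test_that("edge cases: zero successes and zero backward steps", {
  none <- step_statistics(tibble::tibble(success = rep(FALSE, 5),
                                         abs_step = 0, anchor = 1))
  expect_true(is.na(none$summary$forward_backward_ratio))
  expect_true(is.na(none$summary$mean_step))
  fwd <- step_statistics(tibble::tibble(success = rep(TRUE, 4),
                                        abs_step = c(1, 2, 2, 5), anchor = 1))
  expect_equal(fwd$summary$forward_backward_ratio, Inf)
  expect_error(step_statistics(tibble::tibble(success = logical(),
                                              abs_step = numeric())),
               "empty")
})

test_that("large-step mode restricts to steps of at least two beads", {
  ev <- tibble::tibble(
    success = rep(TRUE, 10),
    abs_step = c(1, 1, 1, 1, 2, 3, 3, 3, 5, -2),
    anchor = 1
  )
  m <- large_step_mode(ev)
  expect_equal(m$mode_beads, 3L)
  expect_equal(m$mode_nm, 30)
  expect_equal(m$n_large, 5L)  # steps >= 2 beads
  empty <- large_step_mode(tibble::tibble(success = TRUE, abs_step = 1,
                                          anchor = 1))
  expect_true(is.na(empty$mode_beads))
})

test_that("extrusion velocity: exact slope, unit conversion, random-walk flag", {
  t <- seq(0, 10000, by = 100)
  tr <- mk_trace(cbind(0.02 * t, 0.02 * t))
  v <- extrusion_velocity(tr, boot = 10)
  expect_equal(v$velocity, 0.02, tolerance = 1e-10)
  expect_false(v$nonlinear)
  expect_equal(v$velocity_kbp_s, 0.02 * 30 / 2.3e-4 / 1000,
               tolerance = 1e-10)
  # 0.01 beads/tau_B is ~1.3 kbp/s
  expect_equal(round(extrusion_velocity(mk_trace(cbind(0.01 * t, 0.01 * t)),
                                        boot = 0)$velocity_kbp_s, 1), 1.3)
  # random-walk ensemble: tiny velocity, flagged nonlinear
  rw <- reflected_walk_traces(60, 100, seed = 3)
  vrw <- extrusion_velocity(rw, boot = 0)
  expect_true(vrw$nonlinear)
  expect_lt(abs(vrw$velocity), 0.02)
})

test_that("gamma_sweep degenerate case returns its single angle as optimum", {
  cfg <- desk_config(n_beads = 40, run_time = 400, equilibration_time = 100,
                     replicates = 2, seed = 6)
  sw <- gamma_sweep(cfg, gammas = 120)
  expect_equal(nrow(sw), 1)
  expect_equal(attr(sw, "argmax_gamma"), 120)
  expect_equal(glance(sw)$argmax_gamma, 120)
  expect_s3_class(tidy(sw), "tbl_df")
  expect_true(all(c("success_probability", "velocity") %in%
                    tidy(sw)$statistic))
})
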