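# Independent brute-force implementations used as oracles. These are written
# directly from the capture-rule definition and share no code with the
# simulation kernel.

brute_force_candidates <- function(pos, anchor, head, gamma, shell = c(1, 4),
                                   jump_cap = 5,
                                   variant = "two_spring_asym",
                                   orientation = "forward") {
  n <- nrow(pos)
  dir <- pos[head, ] - pos[anchor, ]
  if (sqrt(sum(dir^2)) < 1e-9) return(integer())
  s <- sign(head - anchor)
  h_in <- head - s
  apex <- if (variant == "barycentre_axis") {
    a_in <- anchor + s
    colMeans(pos[c(anchor, head, a_in, h_in), ])
  } else {
    pos[head, ]
  }
  cosg <- cos(gamma / 2 * pi / 180)
  out <- integer()
  for (j in seq_len(n)) {
    if (j < 2 || j > n - 1) next
    if (j == head || j == h_in) next
    if (abs(j - head) > jump_cap) next
    if (abs(j - anchor) < 3) next
    p <- pos[j, ] - apex
    d <- sqrt(sum(p^2))
    if (d < shell[1] || d > shell[2]) next
    cosang <- sum(dir * p) / (sqrt(sum(dir^2)) * d)
    keep <- if (orientation == "forward") cosang >= cosg else cosang <= cosg
    if (keep) out <- c(out, j)
  }
  out
}

# reflected +/-1 random walk traces (reflecting wall at 0), the null model
# for isotropic capture
reflected_walk_traces <- function(n_reps, n_steps, dt_attempt = 100,
                                  seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_reps), function(r) {
    l <- numeric(n_steps + 1)
    for (i in seq_len(n_steps)) {
      l[i + 1] <- abs(l[i] + sample(c(-1, 1), 1))
    }
    tibble::tibble(replicate = r, time = (0:n_steps) * dt_attempt,
                   loop_length = l)
  }))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  qr.Q(qr(m)) * sample(c(-1, 1), 1)
}

# quick equilibrated test chain, cached per session
test_chain <- local({
  cache <- list()
  function(n = 60, seed = 4, duration = 300) {
    key <- paste(n, seed, duration)
    if (is.null(cache[[key]])) {
      cfg <- desk_config(n_beads = n, replicates = 2, seed = seed)
      pol <- make_polymer(n, "random_walk", seed = seed)
      cache[[key]] <<- equilibrate(pol, cfg, duration = duration)
    }
    cache[[key]]
  }
})

# ---- pre-formed loop protocol -----------------------------------------
# Loads an SMC on a 3D-proximate bead pair at least `min_sep` beads apart
# along the chain, so the stationary capture bias of a developed loop can
# be measured without the small-loop growth transient.
load_preformed <- function(pol, cfg, rep, min_sep = 25) {
  pos <- pol$positions
  d <- as.matrix(dist(pos))
  idx <- which(d < 4, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2] &
               abs(idx[, 1] - idx[, 2]) >= min_sep, , drop = FALSE]
  if (nrow(idx) == 0) return(NULL)
  k <- smcloop:::with_seed(smcloop:::derive_seed(cfg$seed, rep, 1),
                           sample.int(nrow(idx), 1))
  smc_state(anchor = idx[k, 2], head = idx[k, 1], cfg)
}

# capture-bias statistics for one variant on pre-formed loops
preformed_bias <- function(variant, gamma, seed, reps = 5, n_beads = 160,
                           run_time = 4000, equil = 1500,
                           field = external_field("none")) {
  cfg <- desk_config(n_beads = n_beads, gamma = gamma, variant = variant,
                     run_time = run_time, replicates = reps, seed = seed,
                     field = field, equilibration_time = equil)
  evs <- list()
  for (rep in seq_len(reps)) {
    pol <- make_polymer(n_beads, "random_walk", seed = seed * 17 + rep)
    if (cfg$field$mode %in% c("slab", "slab+tether")) {
      # start inside the slab, as the main pipeline does
      bound <- max(cfg$field$slab_gap / 2 - 0.5, 0.1)
      z <- pol$positions[, 3]
      if (max(abs(z)) > 0) {
        pol$positions[, 3] <- z / max(1, max(abs(z)) / (0.9 * bound))
      }
    }
    pol <- equilibrate(pol, cfg, replicate = rep)
    smc <- load_preformed(pol, cfg, rep)
    if (is.null(smc)) next
    pol <- run_dynamics(pol, cfg, duration = 500, smc = smc,
                        replicate = rep, stream = 5)
    res <- smcloop:::cpp_extrude(
      polymer_positions_of(pol), unclass(smcloop:::config_ff(cfg)),
      smcloop:::smc_to_cpp(smc), run_time = cfg$run_time, dt = cfg$dt,
      attempt_interval = cfg$attempt_interval,
      field = smcloop:::field_to_cpp(cfg$field),
      seed = cfg$seed, replicate = rep)
    a <- smc$anchor
    evs[[length(evs) + 1]] <- tibble::tibble(
      replicate = rep, success = as.logical(res$success),
      abs_step = abs(a - res$new_head) - abs(a - res$old_head), anchor = a)
  }
  step_statistics(dplyr::bind_rows(evs))$summary
}

polymer_positions_of <- function(pol) pol$positions
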