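# smcloop

Coarse-grained simulation of DNA loop extrusion by SMC complexes
(condensin, cohesin) with **anisotropic DNA segment capture**.

## The problem

SMC complexes extrude DNA loops, yet the capture step at the heart of
scrunching / segment-capture models is a 3D search with no built-in sense
of direction: a complex that grabs any nearby DNA segment will as often
grab the inside of its own loop — shrinking it — as the outside. ATP
hydrolysis breaks detailed balance (captured segments are pulled in, never
pushed out), but that alone only produces a random walk of the loop
length. `smcloop` implements and analyses a model in which one geometric
ingredient fixes this: the hinge searches a *truncated open spherical
sector* — aperture γ (the "grabbing angle"), axis running from the DNA
anchored at the safety belt through the heads-bound segment, radial reach
1–4 bead diameters (10–40 nm). For γ < 360° loop growth spontaneously
self-rectifies; at γ = 360° it degrades to a reflected random walk.

The package is for quantitative biologists and polymer physicists who
want to simulate the model, sweep its geometry, and compute the
statistics used to compare it against single-molecule experiments.

## The model in brief

DNA: a bead-spring chain (N = 400 beads of σ = 10 nm ≈ 30 bp by default)
with WCA excluded volume, FENE bonds (k = 30 ε/σ², R₀ = 1.5 σ) and a
Kratky–Porod bending penalty giving persistence length l_p = 5 σ = 50 nm.
SMC: two weak harmonic springs (k = 5 ε/σ², r₀ = 1.6 σ) joining the
anchor bead n_a and head bead n_h and their loop-side neighbours. Every
Δt = 100 τ_B a capture is attempted: a bead r is capturable iff

    cos∠(dir, pos) ≥ cos(γ/2),   σ ≤ |pos| ≤ 4σ,
    |index − n_h| ≤ 5,  |index − n_a| ≥ 3,

with dir = r_h − r_a and pos = r − r_h; one candidate is chosen uniformly
and becomes the new head (the stretched spring then relaxes — the
ATP-like, irreversible work step). The oriented loop length l = n_a − n_h
and the per-attempt event log yield every reported statistic: RMS
extruded length and its growth exponent, step-size distributions, capture
success probability, extrusion velocity, and the γ-sweep trade-off
(success rises with γ, step size falls, velocity peaks in between).
Five structural variants (two-spring baseline, one-spring,
barycentre-axis, asymmetric/symmetric torsion constraints) probe which
local asymmetries the rectification needs.

Dynamics are Langevin at k_BT = 1 with per-bead friction ξ = 1 (D =
1 σ²/τ_B, the definition of the Brownian time; 1 τ_B ≈ 0.23 ms), BAOAB
integration at dt = 0.01 τ_B; a strict overdamped Euler–Maruyama mode is
available for small timesteps. Details and design rationale are in the
methods vignette (`vignettes/loop-extrusion-model.Rmd`).

## Worked example

```r
library(smcloop)

cfg <- desk_config(gamma = 120, replicates = 4, seed = 7)  # N = 200 beads
sim <- simulate_extrusion(cfg)

step_statistics(sim)
#> <smc_step_stats> 400 attempts | success 51.0% | s = +1.25 beads (+12 nm) | fwd:bwd 2.58

extrusion_velocity(sim)[, 1:4]
#> # A tibble: 1 x 4
#>   velocity      se velocity_bp_s velocity_kbp_s
#>      <dbl>   <dbl>         <dbl>          <dbl>
#> 1  0.00511 0.00211          667.          0.667
```

Read: at γ = 120° about half of the capture attempts find an eligible
segment; successful steps average +1.25 beads (12.5 nm of DNA) with
forward steps outnumbering backward ones ~2.6:1, so the loop grows
steadily — rectified extrusion at roughly 0.7 kbp/s in physical units.
Rerunning the same `cfg` reproduces the event log exactly;
`autoplot(sim)` draws the loop-length traces, and

```r
sw <- gamma_sweep(desk_config(replicates = 8),
                  gammas = c(60, 120, 180, 240, 300, 360))
glance(sw)         # velocity-optimal grabbing angle
autoplot(sw, "tradeoff")
```

reproduces the success/step-size trade-off with its velocity optimum at
an intermediate angle.

A thin command-line front end wraps the same functions:

```sh
inst/exec/smcloop simulate --config cfg.yaml --out runs/a
inst/exec/smcloop sweep --gammas 60,180,360 --out runs/sweep
```

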