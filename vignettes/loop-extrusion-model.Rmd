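---
title: "An anisotropic segment-capture model of SMC loop extrusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An anisotropic segment-capture model of SMC loop extrusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(smcloop)
```

## The scientific question

Structural-maintenance-of-chromosomes (SMC) complexes — condensin, cohesin,
SMC5/6 — organise genomes by extruding DNA loops. A long-standing puzzle is
*rectification*: how a complex that captures 3D-proximal DNA segments, with
no intrinsic knowledge of "forward", grows a loop persistently instead of
letting it shrink back. Breaking detailed balance (the ATP-driven capture
cycle pulls DNA in and never pushes it out) is necessary but not
sufficient: an isotropic searcher that captures any nearby segment will as
happily grab DNA *inside* the loop, shrinking it, and the loop length
performs a random walk.

`smcloop` implements a coarse-grained molecular-dynamics model in which one
extra geometric ingredient — an *anisotropic* capture region, motivated by
AFM observations that the SMC hinge extends orthogonally to the bound DNA
within a limited angular sector — is enough to make loop growth
self-rectifying. The package simulates the model, reproduces its
statistical signatures (random walk at isotropic capture, linear rectified
growth at restricted angles, a velocity optimum at intermediate angles, a
step-size/success-rate trade-off), and compares five structural variants of
the SMC anchoring geometry.

## The polymer model

DNA is a linear bead-spring chain of `n_beads` beads (default 400) of
diameter $\sigma$ = 10 nm $\approx$ 30 bp, giving a contour length of about
4 µm (12 kbp). All computation uses reduced units: $\sigma$ (length),
$\epsilon = k_BT$ (energy) and the Brownian time $\tau_B$ of one bead
(time); conversions to nm, bp and seconds happen only in observables, via
`unit_system()` (one $\tau_B$ maps to $2.3\times10^{-4}$ s so that a
$10^5\,\tau_B$ run is about 23 s).

Three bonded/non-bonded terms define the chain:

* **Excluded volume** — the Weeks–Chandler–Andersen (WCA) potential
  $U_{\mathrm{WCA}}(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] +
  \epsilon$ for $r \le 2^{1/6}\sigma$, zero beyond: purely repulsive,
  $C^1$ at the cutoff.
* **Connectivity** — FENE bonds between consecutive beads,
  $U_{\mathrm{FENE}}(r) = U_{\mathrm{WCA}}(r) - 0.5\,k R_0^2 \ln[1 -
  (r/R_0)^2]$ with $k = 30\,\epsilon/\sigma^2$, $R_0 = 1.5\sigma$. The
  combined bond minimum sits near $0.97\sigma$ and the bond can never
  cross $R_0$ (the kernel aborts if discretisation error ever pushes it
  there).
* **Stiffness** — a Kratky–Porod penalty per bead triplet,
  $U_{\mathrm{KP}}(\theta) = (k_BT\,l_p/\sigma)(1 - \cos\theta)$ with
  $\theta = 0$ for a collinear triplet, giving persistence length
  $l_p = 5\sigma = 50$ nm. (The convention $\theta = 0 \Rightarrow$
  straight is required for $l_p$ to be a persistence length.)

The SMC itself is not a bead: it is a pair of **harmonic springs**,
$U(r) = k(r - r_0)^2$ with $k = 5\,\epsilon/\sigma^2$ and
$r_0 = 1.6\sigma$, deliberately weak to mimic the disordered kleisin
linkage. One spring joins the anchor bead $n_a$ (the Ycg1/Brn1 safety-belt
site, immutable once loaded) to the head bead $n_h$ (the ATPase-head site,
mobile); the second joins their loop-side neighbours. Note the quadratic
form carries no factor $\tfrac12$; the constant is as stated.

## The capture cycle

After loading (a uniformly chosen bead pair closer than $4\sigma$ in 3D
and at least 3 beads apart along the chain), a capture attempt happens
every $\Delta t = 100\,\tau_B$:

1. The capture axis is $\mathrm{dir} = r_h - r_a$; the capture region is a
   truncated open spherical sector with apex at the head: a bead at
   $\mathrm{pos} = r - r_h$ is *capturable* if its angle from the axis is
   at most $\gamma/2$, and $\sigma \le |\mathrm{pos}| \le 4\sigma$ (the
   10–40 nm hinge reach).
2. 1D filters: at most `jump_cap` (5) beads from the head along the chain,
   at least 3 beads from the anchor, not the current head pair, and not a
   terminus bead.
3. One candidate is chosen uniformly at random; the head springs are
   deleted and re-formed on the captured bead (stretched, then relaxing
   under the dynamics — the work-extracting, ATP-like step). If no bead
   qualifies, nothing changes.

The cycle is irreversible — captured segments are only ever pulled toward
the anchor — so detailed balance is broken by construction, yet at
$\gamma = 360^\circ$ (isotropic capture) the oriented loop length
$l = n_a - n_h$ still performs a random walk. Rectification requires
$\gamma < 360^\circ$.

**Inequality orientation.** Written as a cosine condition, the angular
rule is $\cos\angle(\mathrm{dir}, \mathrm{pos}) \ge \cos(\gamma/2)$: a
forward cone that widens with $\gamma$ and reduces to the full shell at
$\gamma = 360^\circ$, consistent with the isotropic limit described above.
The opposite orientation (which would select a backward *anti*-cone and
nearly nothing at $360^\circ$) is retained behind
`cone_orientation = "printed"` purely for auditability.

## Structural variants

`sim_config(variant = ...)` selects among five anchoring geometries:

| variant | springs | capture region | torsion term |
|---|---|---|---|
| `two_spring_asym` | anchor–head + loop-side neighbours | apex at head | — |
| `one_spring` | anchor–head only | apex at head | — |
| `barycentre_axis` | two springs | apex at the barycentre of the four bonded beads | — |
| `dihedral_asym` | anchor–head only | apex at head | asymmetric |
| `dihedral_sym` | two springs | apex at head | symmetric |

The torsion terms penalise the relative orientation of the DNA segments
bonded at the anchor and head. Their angle definitions are a design choice
of this package (the geometric intent — all boundary segments orthogonal
to the capture axis — admits several parameterisations): for each bonded
segment vector $b$, $\delta$ is its deviation from orthogonality to the
axis $u$ and costs $(k_BT l_p/\sigma)(1 - \cos\delta)$; for each segment
pair, $\varphi$ is the angle between their projections onto the plane
orthogonal to $u$ and costs $5\epsilon\,\varphi^2$. The asymmetric form
uses the two loop-side segments ($\delta_1, \delta_2, \varphi_1$); the
symmetric form adds the two outward segments
($\delta_3, \delta_4, \varphi_2$), restoring the local symmetry and — as
the simulations show — destroying rectification. Similarly, the
barycentre variant is stated only as "the axis passes through the
barycentre"; we implement it as the cone apex moved from the head to the
barycentre of the four bonded beads, keeping the axis direction, which is
the minimal symmetric repositioning.

## Dynamics and numerics

The chain evolves by Langevin dynamics at $k_BT = 1$ with friction
$\xi = 1$ per bead, so the single-bead diffusion coefficient is
$D = k_BT/\xi = 1\,\sigma^2/\tau_B$ — the definition of $\tau_B$.

Two integrators are provided:

* **BAOAB (default)** — inertial Langevin with unit bead mass, splitting
  kick/drift/Ornstein–Uhlenbeck, at $dt = 0.01\,\tau_B$. Velocities
  decorrelate within $m/\xi = 1\,\tau_B$, so on every timescale relevant
  to capture statistics (the attempt interval is $100\,\tau_B$) the motion
  is indistinguishable from overdamped diffusion, while the integrator
  resolves the stiff bond oscillation (period
  $2\pi\sqrt{m/\kappa} \approx 0.2\,\tau_B$ at the effective bond
  curvature $\kappa \approx 10^3\,\epsilon/\sigma^2$) comfortably.
* **Overdamped Euler–Maruyama** (`integrator = "euler"`) — the strict
  Brownian update $\Delta x = (F/\xi)\,dt + \sqrt{2k_BT\,dt/\xi}\,\eta$.
  Against the same bond stiffness this scheme is stable only for
  $dt \lesssim 5\times10^{-4}\,\tau_B$ (the compressed-bond side of the
  WCA wall has curvature approaching $5\times10^3$), which validation
  enforces. It is used where the exact overdamped displacement law is the
  point (e.g. the free-bead diffusion checks); production runs use BAOAB
  because it buys a ~20-fold cost reduction at identical configurational
  statistics.

Random numbers come from xoshiro256++ streams (ziggurat normals) seeded
from `(seed, replicate, stream)`, with separate streams for thermal noise,
loading, capture selection and chain generation: capture decisions are
reproducible independently of the dynamics, replicates are independent,
and a configuration reruns bit-for-bit on one platform.

**Initial conformations and equilibration.** Chains start as
self-avoiding random walks whose joint angles are drawn from the
Boltzmann weight of the bending term (so stiffness statistics are right
from the start), then pass a displacement-capped steepest descent (which
never increases the energy) and `equilibration_time` of dynamics before
loading. The default is $10^4\,\tau_B$ at full scale and
$2\times10^3\,\tau_B$ in `desk_config()`; the bond-vector correlation
test recovering $l_p = 5\sigma \pm 10\%$ is the evidence that this
protocol decorrelates the chain adequately.

**Walls and tethers.** Quasi-2D runs confine all beads between two walls
at $z = \pm$ gap/2 (default gap $3\sigma$; the force is harmonic beyond a
half-bead margin so beads stay strictly inside the gap, leaving about one
bead diameter of free vertical range — quasi-2D relative to the
$4\sigma$ capture reach). Tethered runs pull the two end beads apart
with a constant force along x (1 $\epsilon/\sigma \approx 0.4$ pN).

## Observables

* `rms_extruded_length()` — $\langle l\rangle(t) = \langle[n_a -
  n_h]^2\rangle^{1/2}$ across replicates with bootstrap errors;
  `fit_scaling_exponent()` fits $\log\langle l\rangle$ vs $\log t$. The
  default window is the last decade of the run: it excludes the loading
  transient (the first attempts, where $l$ is pinned near its loading
  value of 3–4 beads) which otherwise biases the exponent downward in
  short runs.
* `step_statistics()` — success probability, signed step histogram
  (1-bead = 10 nm bins, the natural lattice of the capture rule), the
  mean step $s = \sum_i \mathrm{sign}(i) S_i / N$ over *successful* steps
  (taking $N$ as all attempts is the documented alternative; successful
  steps match the per-step character of the printed formula), and the
  forward:backward count ratio. Steps are changes of $|l|$, so "forward"
  always means loop growth.
* `large_step_mode()` — the mode of the forward-step histogram restricted
  to $\ge 2$ beads, the statistic compared against the ~50 nm steps seen
  in single-molecule experiments.
* `extrusion_velocity()` — least-squares slope of mean $|l|(t)$ over
  10–60% of the run (excluding the loading transient and end-of-chain
  saturation; the window is a package choice), with bootstrap errors and
  a non-linearity flag (log–log exponent < 0.8) marking random-walk-like
  ensembles whose "velocity" is not meaningful.
* `gamma_sweep()` — the full pipeline per grabbing angle, assembling the
  success/step-size trade-off and the velocity optimum.

## What the generator emulates — and what it does not

The synthetic chains reproduce the mechanical regime the model needs:
correct excluded volume, connectivity, stiffness and diffusive dynamics of
naked DNA at 10 nm resolution. They do not include sequence heterogeneity,
twist/supercoiling (beyond the optional torsion penalties at the SMC),
hydrodynamic interactions, crowding, nucleosomes or multiple SMCs. Passing
tests therefore demonstrate properties of the capture *model*, not
predictions for chromatin in vivo; the mapping of $\tau_B$ to seconds, in
particular, assumes free DNA in buffer.

## Behaviour at reduced scale

Three finite-size effects matter when the model is run far below the
full-scale conditions, and they shape how the packaged checks are set up:

* **The small-loop regime rectifies everything.** Just after loading the
  loop is 3--5 beads long, and the bookkeeping rule that candidates stay
  at least 3 beads from the anchor then excludes essentially every
  inside-loop bead — so the head is *forced* outward (a measured drift of
  about +2.7 beads per successful attempt while $|l| \lesssim 8$),
  whatever the variant geometry. The structural-variant comparison is
  therefore run on *pre-formed* loops: an SMC is installed on a
  3D-proximate bead pair at least 25 beads apart along the chain,
  relaxed, and only then probed. In that developed-loop regime the
  asymmetric constructions keep a clear forward capture bias while the
  symmetric ones are random-walk-like, which is the substance of the
  variant comparison; the quasi-2D check likewise compares per-attempt
  extrusion rates on pre-formed loops across grabbing angles, since
  full desk-scale slab runs never leave the small-loop regime.
* **The loading state contaminates the raw null curve.** Loading picks a
  uniformly random 3D-proximate bead pair, whose 1D separation is
  heavy-tailed (an equilibrated coil has occasional contacts ~100 beads
  apart), and the early anchor-exclusion drift further inflates the
  curve's low end. Both nuisances vanish at full scale but dominate the
  raw RMS extruded length in short runs, so the random-walk check at
  $\gamma = 360^\circ$ fits the RMS *displacement*
  $\langle(l(t) - l(0))^2\rangle^{1/2}$ — asymptotically identical to
  the RMS extruded length and cleanly diffusive at every scale (per-step
  autocorrelation $\approx -0.08$, mean step $\approx 0$ for
  $|l| > 8$).
* **The step-size lattice is shell-limited at its top.** A forward step
  of 5 beads requires the bead five bonds away — typical 3D distance
  about $4.3\sigma$ at $l_p = 5\sigma$ — to fall inside the $4\sigma$
  capture shell, which needs a locally bent conformation; 4-bead
  distances fit comfortably. The forward step-size distribution at
  $\gamma = 60^\circ$ therefore peaks at 4 beads (40 nm) with the 5-bead
  (50 nm) bin as a shoulder, while *across angles* the probability of
  cap-sized 50 nm steps is still maximal at $\gamma = 60^\circ$ — the
  trend that matches the large steps seen in single-molecule
  experiments.

## Problem sizes used by the tests and the acceptance script

Full-scale study conditions (N = 400, $10^5\,\tau_B$, 30 replicates) take
hours; the packaged checks run reduced versions chosen so every statistic
keeps a comfortable signal-to-noise margin: unit and property tests use
chains of 40–100 beads and runs of $10^2$–$10^4\,\tau_B$; the acceptance
analyses use `desk_config()`-like settings (N = 100–200,
$10^4\,\tau_B$-scale runs, 8–25 replicates, at least $10^3$ pooled capture
attempts for probability estimates). The reproduction script
(`scripts/acceptance.R`) states its own sizes in its output.

## Known limitations

* The torsion-variant angle geometry and the barycentre apex are package
  design choices (see above); other parameterisations of the same stated
  intent may shift variant-level quantitative results.
* The inertial integrator slightly perturbs dynamical (not static)
  quantities below ~1 $\tau_B$; nothing the package reports lives there.
* Dihedral-variant forces are computed by central differences of the term
  energy (the orthogonality penalty has a derivative cusp where a segment
  aligns with the axis); force/energy consistency is verified by tests
  against an independent energy implementation.
* Single SMC per chain; no Z-loops, bypassing or roadblocks.
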