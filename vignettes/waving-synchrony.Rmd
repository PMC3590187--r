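---
title: "Modeling waving-display synchrony in fiddler crab colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling waving-display synchrony in fiddler crab colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crabsync)
```

## The model and its assumptions

`crabsync` simulates a colony of male fiddler crabs performing rhythmic
claw-waving displays. The model makes five structural assumptions:

1. **Burrow-bound males on a lattice.** Each male sits at one site of an
   `L × L` square lattice (the area around his burrow) and never moves.
   `round(ρL²)` sites are occupied uniformly at random.
2. **Scalar displacement, discrete time.** The waving display of male `i`
   is reduced to a single displacement variable `x_n^i ∈ [0, 1]` per time
   step. One wave cycle corresponds to the period of the orbit: a
   period-two orbit is a complete up–down wave every two steps; an
   aperiodic (chaotic) orbit is a wave whose amplitude never repeats
   exactly — a plausible reading of natural variability, not a different
   kind of motion.
3. **Logistic waving dynamics.** In isolation a male follows the logistic
   map `f_µ(x) = µx(1 − x)`. The constant `µ` tunes waving complexity:
   stable fixed point below 3 (no visible wave), period doubling from 3 to
   ≈ 3.57, chaos beyond, with periodic windows (the widest, period three,
   near 3.83).
4. **Sector-shaped attention.** Male `i` attends only to males inside a
   circular sector of reach `R` and opening angle `θ` anchored at his
   site. Orientation is fixed before the dynamics start, either uniformly
   at random (**M1**) or so that the number of visible males is maximal
   (**M2**). The coupled update is a convex combination with weight `D`:
   `x' = (1 − D) f_µ(x_i) + D f_µ(X̄_i)`, where `X̄_i` is the (plain or
   inverse-distance-weighted) mean displacement over the sector. Males
   with empty sectors (**leaders**) run the pure logistic map.
5. **Absorbing boundaries.** The lattice has no wrap-around. By default a
   sector overhanging the edge is simply clipped (the missing area
   contains nobody). A stricter alternative (`boundary = "literal"`), in
   which a male whose sector leaves the lattice receives no coupling at
   all, is provided as a switch; it changes only edge behavior and none of
   the package's reported central-subgrid statistics materially.

What the update applies the map *to* deserves a note: the coupling term is
`D·f_µ(X̄_i)` — the map of the neighborhood mean — not the mean of the
mapped neighbors. This is the form whose two-individual reduction has the
amplitude-difference multiplier `(1 − 2D)µ(1 − x_i − x_j)`, which the pair
theory (below) and the package's cross-checks rely on. The alternative
"mean of maps" form, which agrees with it on single-neighbor graphs, is
available as `coupling_form = "mean-of-map"` for sensitivity analyses.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `mu` | waving complexity (logistic constant) | 3.2 | period-two regime |
| `D` | coupling strength | 0.5 | `0` decouples; `0.5` synchronizes a mutual pair in one step |
| `L` | lattice width (sites) | 30 | |
| `L_c` | width of the central statistics subgrid | 10 | boundary-effect control |
| `rho` | occupancy density | 0.4 | population `round(ρL²)` |
| `theta` | attention angle (degrees) | 60 | `360` makes M1 ≡ M2 |
| `R` | attention reach (site units) | 3 | |
| `n_transient` | discarded steps | 500 | past all observed transients in the periodic regimes |
| `n_l` | measurement window (steps) | 500 | the correlation time lag |
| `s_t` | replicates per estimate | 500 | reduce for desk-scale runs (see below) |

## Orientation rules

Under M2 a male maximizes the number of neighbors inside his sector over a
continuous orientation `φ`. Because the count only changes when a sector
edge crosses a neighbor direction, the maximum is always attained at an
orientation whose edge touches some neighbor direction; the implementation
therefore searches the finite candidate set {direction to each neighbor}
∪ {those directions ± θ/2} and provably attains the continuous optimum
(the test suite checks this against an independent maximum-points-in-arc
sweep). Orientations covering *distinct but equally large* neighbor sets
are tied; the tie is resolved uniformly at random, or — under
`tie_rule = "similarity"` — in favor of the set whose mean displacement at
orientation time is closest to the male's own, using the initial
displacements since orientation precedes the dynamics. A male with nobody
in reach orients at random; he is a leader, and by symmetry of distance he
also appears in no other male's field, which is why the M2
leaders-per-follower statistic is exactly zero.

Both the distance and the angular sector tests are inclusive
(`d ≤ R`, offset `≤ θ/2`), with an absolute tolerance of `1e-9` degrees on
the angular comparison so that an orientation constructed to place a
neighbor exactly on the sector edge keeps that neighbor inside despite
floating-point rounding.

## Synchrony statistics

`r_i` is the mean Pearson correlation between male `i`'s measured window
and each watched neighbor's window. Two conventions keep it defined
everywhere:

* **Degenerate windows.** Below `µ = 3` all trajectories converge to the
  fixed point `1 − 1/µ` and have (numerically) zero variance, where the
  Pearson correlation is undefined. A window with standard deviation
  below `1e-8` is treated as constant: two constant windows correlate 1
  if their means agree to the same tolerance and 0 otherwise; a constant
  against a varying window correlates 0. The fixed-point regime therefore
  reports full synchrony (`⟨r⟩ = 1`), which is the scientifically sensible
  reading of a colony in which every male sits still at the same value.
* **Leaders.** `r_i` is an average over an empty set for a leader; leaders
  are excluded from `⟨r⟩` (not counted as zero), and the number of
  exclusions is reported. Counting them as zero would cap `⟨r⟩` well below
  1 even in the fixed-point regime, contradicting the statistic's purpose.

`⟨r⟩` averages `r_i` over followers inside the centered `L_c × L_c`
subgrid, then over `s_t` replicates seeded independently from one master
seed, so replicates are individually reproducible and order-independent.

## Leaders per follower: two counts

Followers driven by two or more *unsynchronized* leaders cannot lock to
both, which is the structural explanation for the asynchrony band at
intermediate densities under M1. The package reports two versions of the
"leaders per follower" diagnostic, because they answer different
questions:

* `leaders_per_follower` — leaders **directly inside** a follower's field
  of attention. This is the contract used by the acceptance script. It is
  mathematically small: its expectation is of order
  `a·ρ·(1 − ρ)^a` for a sector holding `a` sites, which never exceeds
  ≈ 0.5 for any `a`, peaking near `ρ = 1/(a + 1)`.
* `leaders_per_follower_influence` — distinct leaders from which a
  directed chain of attention reaches the follower. This transitive count
  exceeds 1 precisely over the intermediate-density band
  (≈ 1.9 at `ρ = 0.30` under the default geometry) and is the version that
  matches the magnitude of the published density curves for this model
  family; at high density it grows large because a single leader's
  influence propagates through the well-connected lattice.

Both are computed from the same directed network; neither involves any
tunable constant.

## Two-individual theory

A mutually watching pair reduces to
`Δ_{n+1} = (1 − 2D) µ (1 − x_i − x_j) Δ_n` for the amplitude difference;
a leader–follower pair to `Δ_{n+1} = (1 − D) µ (1 − x_i − x_j) Δ_n`.
Since `|1 − x_i − x_j| ≤ 1` on the unit square, `ν = |1 − 2D|µ < 1`
(respectively `(1 − D)µ < 1`) guarantees geometric synchronization — a
sufficient condition only. `estimate_sync_threshold()` quantifies the gap:
for each grid `D` it iterates `trials` random initial pairs up to
`max_iter` steps and declares synchrony at `|Δ| < tol`; the reported
threshold is the smallest grid value from which *every larger grid value*
also synchronizes in all trials, so an isolated lucky cell below a
desynchronization window is never reported. At `µ = 3.2` (bidirectional,
grid step 0.002, 200 trials, `max_iter = 1e5`, `tol = 1e-9`) the estimate
is ≈ 0.06, far below the sufficient condition's `D ≈ 0.34`. The lattice
dynamics on two-node networks agrees with this closed-form update to
round-off at every step, which the test suite uses as a cross-check
between the two modules.

## Numerical choices

* **Period detection** reports the smallest `p ≤ p_max = 64` with
  `|x_{n+p} − x_n| < tol` across the sampled tail (`tol = 1e-8` for the
  single map, `1e-6` for lattice windows, whose transients are shorter).
  A tail matching no period is flagged aperiodic — the operational
  version of "the period approaches infinity" at the accumulation point.
* **Scan transient = 20 000 steps.** Next to a bifurcation the dynamics
  suffers critical slowing-down: one grid step (0.005) below `µ = 3` the
  contraction factor is ≈ 0.995, so 2 000 steps leave a residual of
  ≈ 4·10⁻⁵, misclassifying the point; 20 000 vectorized steps cost well
  under a second for the whole grid and push every off-bifurcation
  residual below `tol`.
* **Chaos onset** on a scan is the first grid point opening a run of at
  least two consecutive aperiodic flags. A grid point landing *exactly on*
  a bifurcation (e.g. `µ = 3.0`) is neutrally stable, converges only
  algebraically, and is honestly flagged aperiodic by any finite-transient
  detector; requiring two consecutive flags discards such isolated
  marginal points and yields 3.57 on the 0.005 grid.
* **Initial displacements** for lattice runs are i.i.d. uniform on (0, 1)
  per individual. The single-map figures conventionally use `x_0 = 0.1`.
* **Distance weighting** (optional) uses weights `∝ 1/d`; the exponent is
  exposed (`weight_exponent`) since plausible perceptual models differ.
* **Endpoints.** `D = 1` (pure neighborhood drive) and `µ = 4`, `x ∈ {0, 1}`
  are permitted; all remain within `[0, 1]` because the update is a convex
  combination of values in `[0, µ/4]`.

## Problem sizes

Paper-grade estimates of `⟨r⟩` in this model family conventionally use
`s_t ≥ 500` replicates and thousands of networks for density curves. The
package defaults keep that convention, while the shipped tests and the
acceptance script use desk-scale sizes chosen so that every Monte-Carlo
estimate is still well inside its stated tolerance: 500 placements for
network statistics, 50–200 replicates for lattice synchrony (Monte-Carlo
standard error of `⟨r⟩` ≈ 0.01 at `s_t = 50`), 200 trials for the pair
threshold. `replicate_network_stats()` and `global_correlation()` take
the replicate count as an argument, so full-scale runs are one keystroke
away.

## What the generator does and does not emulate

The simulator generates its own populations; no field data enter. It
captures the features the model family is about — local sector-limited
visual coupling, density-dependent network structure, leader-driven
asynchrony, symmetry breaking into synchronized neighborhoods. It does
**not** emulate: male movement between burrows, heterogeneous individual
quality (per-male `µ` or `D`), background visual noise, female presence,
or any physiology of the compound eye. Passing tests therefore validate
the implementation of the model, not the model's fidelity to any
particular crab colony.

## Known limitations

* The synchronous update makes time implicitly discrete; phenomena tied
  to continuous-time phase response (e.g. Kuramoto-style partial
  entrainment) are outside the model class.
* `⟨r⟩` is a linear correlation; two males waving with the same period but
  a constant phase lag of half a cycle score −1, and amplitude-zero
  (constant) waving scores via the degenerate convention. Alternative
  synchrony orders (vector strength, phase histograms) are not provided.
* At densities near 1 with `θ = 360°` the interaction graph is nearly
  complete and the sparse-matrix representation loses its advantage;
  runtimes grow accordingly.
* The literal boundary switch uses the exact sector support function to
  decide whether a sector leaves the lattice; for `θ > 180°` the sector is
  non-convex but the support-function test remains exact, since only axis
  extremes matter against a box.
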