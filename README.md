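# crabsync

Male fiddler crabs (*Uca* spp.) defend burrows in dense intertidal colonies
and court females with rhythmic waving of their greatly enlarged claw.
Neighboring males often wave in synchrony, forming local "waving
neighborhoods". `crabsync` is a simulator for studying how such synchrony
can emerge from purely local visual interactions: it implements a spatially
explicit coupled logistic-map model of a waving colony, the network
diagnostics that explain when synchrony fails, and the closed-form theory
for two interacting individuals.

The package is aimed at behavioral ecologists and complex-systems
researchers who want a tested, scriptable, fully reproducible
implementation of this model family for parameter sweeps and hypothesis
exploration.

## The model

Each of `round(ρL²)` males occupies a distinct site of an `L × L` lattice.
Male *i*'s claw displacement `x_n^i ∈ [0,1]` evolves by the coupled
logistic map

```
x_{n+1}^i = (1 − D) f_µ(x_n^i) + D f_µ(X̄_n^i),      f_µ(x) = µ x (1 − x)
```

where `X̄_n^i` is the mean displacement of the `N^i` males inside *i*'s
*field of attention* — a circular sector of reach `R` and opening angle `θ`
anchored at *i*'s burrow — and `D ∈ [0,1]` is the coupling constant. A male
with an empty field of attention (a *leader*) follows the pure logistic
map. Two orientation rules are provided: **M1** orients each sector
uniformly at random; **M2** orients it to maximize the number of visible
neighbors (ties broken at random, or by waving similarity). At `θ = 360°`
the two rules coincide.

Synchrony is measured by `r_i`, the mean Pearson correlation between a
male's displacement window and those of the males he watches, averaged
over the males inside a centered `L_c × L_c` subgrid (to avoid boundary
effects) and over `s_t` independently seeded replicates, giving the global
correlation `⟨r⟩`.

For two individuals the amplitude difference `Δ = x^i − x^j` contracts by
`(1 − 2D) µ (1 − x^i − x^j)` (mutual attention) or `(1 − D) µ (1 − x^i −
x^j)` (leader–follower), giving the sufficient synchronization conditions
`ν = |1 − 2D| µ < 1` and `ν = (1 − D) µ < 1`.

## Worked example

```r
library(crabsync)

cfg <- simulation_config(mu = 3.2, D = 0.5, grid = grid_config(30, 10, 0.4),
                         theta = 60, R = 3, model = "M1", s_t = 10)
sim <- run_simulation(cfg, seed = 1)
print(sim$network)
#> interaction network: 360 individuals, 607 directed edges (106 in reciprocal pairs), 52 leaders

network_statistics(sim$network, sim$population)
#> network stats: 52 leaders / 308 followers
#>   leaders per follower (central subgrid): 0.2162
#>   leaders influencing each follower (via chains): 6.568
#>   reciprocal couplings per participant: 1.178
#>   components: 22 (largest 219)

global_correlation(cfg, seed = 1)
#> global correlation <r> = 0.8877 over 10 replicates (334 contributing individuals, window 500)
```

At `µ = 3.2` every male settles on a period-two wave, but with randomly
oriented 60° attention sectors (M1) the colony keeps `⟨r⟩` near 0.9 rather
than 1: followers driven by several unsynchronized leaders cannot lock
together. Re-orienting attention toward neighbors (M2) restores almost
full synchrony under the same conditions:

```r
cfg$model <- "M2"
global_correlation(cfg, seed = 1)$r_global
#> [1] 0.9774142
```

The two-individual theory explains the strong-coupling behavior — at
`D = 0.5` a mutually watching pair synchronizes in a single step
(`ν = 0`) — and the numerical threshold estimator recovers the much lower
empirical onset of pair synchrony:

```r
sync_condition(3.2, 0.5)
#> pair condition (bidirectional): nu = 0 < 1: synchronization guaranteed

estimate_sync_threshold(3.2, D_grid = seq(0.04, 0.09, 0.002),
                        trials = 100, seed = 2)
#> pair synchronization threshold (bidirectional, mu = 3.2): 0.06
#>   (100 trials, max 100000 iterations, tol 1e-09)
```

A command-line interface wraps the same functions for batch sweeps:

```sh
inst/exec/crabsync simulate --seed 1 --out runs
inst/exec/crabsync sweep-phase --mu 3.2 --model M2 --st 50 --seed 1 --out runs
inst/exec/crabsync pair-threshold --mu 3.2 --d-min 0 --d-max 0.2 --d-step 0.002 --seed 1 --out runs
```

## Documentation

The methods vignette (`vignettes/waving-synchrony.Rmd`) describes the
model assumptions, the orientation and boundary conventions, the
degenerate-window correlation convention, all numerical tolerances, and
the known limitations of the simulator.
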