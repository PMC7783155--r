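# spheroidCA

Cellular-automaton simulation and single-cell trajectory quantification of
collective cell migration out of tumour spheroids.

When a glioblastoma spheroid (a packed aggregate of 50–200 µm) is seeded on
a 2-D substrate, its cells invade the surrounding matrix. Small spheroids
disperse almost completely; large ones stay clustered. `spheroidCA` models
this emergent behaviour from four single-cell mechanisms and provides the
statistics used to quantify it from nucleus-tracking data, for
computational biologists studying collective migration, invasion assays and
motility-inhibiting perturbations.

## The model

Cells live on an `m × m` lattice (one site = one cell diameter, 10 µm) with
strict volume exclusion: the occupancy matrix `N` is 0/1. At every
iteration (7 min; 205 iterations cover 24 h) each cell draws a move from a
3×3 probability kernel composed from

* **random movement** — a Gaussian kernel `G` (σ = 2 sites, zero centre,
  sum 1),
* **self-generated chemotaxis** — cells secrete an attractant `u` evolving
  by `∂u/∂t = D∇²u + c₁n − c₂nu`, solved with an explicit five-point
  stencil (λ = D·dt/h², stable for λ ≤ ½); each cell senses the saturated
  gradient `μ = ∇u / (1+3u)²` and the kernel `C` puts `|μ|` on the cardinal
  offset up the dominant gradient axis,
* **mechanical interaction** — `I`, the normalised occupancy convolution
  around the cell (its own contribution removed): a map of attractive
  forces toward neighbours,
* **proliferation** — with probability α a cell divides into a free
  neighbouring site instead of moving.

The composed kernel is `P = r·G + c_f·C + q·I` (clipped at zero,
renormalised only when its total exceeds 1, so `r` alone is the probability
of stepping at all). Moves into occupied sites fail. The calibrated
optimum is `D = 50, c₁ = 0.035, c₂ = c₁/2, c_f = 20, q = 0.3, r = 1,
α = 0`.

The analysis half quantifies trajectories (simulated or TrackMate exports)
by the **mean relative radial migration**

```
meanRRM(t) = ⟨√((xᵢ(t)−x_c)² + (yᵢ(t)−y_c)²)⟩ᵢ / ⟨√((xᵢ(t₀)−x_c)² + (yᵢ(t₀)−y_c)²)⟩ᵢ
```

(1 = clustered, 2 = doubled dispersal), the per-track diffusion coefficient
`d_cell = 1/(4T) Σⱼ Δxⱼ² + Δyⱼ²`, the invasion velocity (OLS slope of the
RRM curve over the first 7.5 h), a 100 µm small/large stratification and
two-sample Kolmogorov–Smirnov comparisons.

## Worked example

```r
library(spheroidCA)

p <- makeParams(seed = 1)          # the calibrated optimum
res <- runSimulation(p, d = 16, nSteps = 205)   # 160 um spheroid, 24 h
tracks <- resultTracks(res)                     # TrackMate-style table, um/s
rrm <- meanRRM(tracks, initialCentroid(tracks))
tail(rrm, 3)
#>       time_h      rrm n_cells
#> 204 23.68333 2.158689     256
#> 205 23.80000 2.153467     256
#> 206 23.91667 2.160334     256
invasionVelocity(rrm, windowH = 7.5)
#> [1] 0.07105848
```

A 160 µm spheroid ends the day at a mean RRM of ≈ 2.2: its cells have, on
average, doubled their radial distance from the centroid, invading at
≈ 0.07 RRM/h during the early linear regime. Switching one mechanism off
measures its contribution — without chemotaxis the same spheroid disperses
further (final RRM 2.286), because the self-generated attractant pulls
cells back toward the colony:

```r
off <- runSimulation(p, d = 16, flags = ablate(mechanismFlags(), "chemotaxis"),
                     nSteps = 205)
```

The estimator side closes the loop on synthetic data:

```r
pd <- populationDcell(brownianTracks(trueD = 0.21, nCells = 200, seed = 42))
sprintf("%.3f +/- %.3f um^2/s", pd$mean, pd$sem)
#> [1] "0.212 +/- 0.001 um^2/s"
```

A shell interface wraps the same functions
(`inst/exec/spheroidca simulate --diameter 160 --steps 205 --seed 1 --out run/`,
plus `cohort`, `analyze` and `fixtures` subcommands); every run writes a
`manifest.json` sufficient to reproduce it bit-identically.

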