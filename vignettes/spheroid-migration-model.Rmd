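---
title: "A modular lattice automaton for spheroid cell migration: model, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A modular lattice automaton for spheroid cell migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidCA)
```

## The model and its assumptions

`spheroidCA` simulates the 2-D invasion of cells out of a tumour spheroid
as a probabilistic cellular automaton. The assumptions are deliberately
minimal:

* Space is a square lattice whose site edge equals one average cell
  diameter (10 µm for U87-like glioblastoma cells), and at most one cell
  occupies a site (volume exclusion). Cells are identical, with no internal
  state beyond their position.
* Time advances in steps of 7 minutes — roughly the time in which a cell
  can displace by its own diameter — and all engine mathematics is
  dimensionless: one length unit is a site, one time unit is the 24-hour
  experiment, so `dt = 7/1440 ≈ 0.00486`. We keep the exact fraction rather
  than a rounded 0.0048 so that 205 iterations land exactly on 24 h.
* Each mechanism contributes a 3×3 weight stencil over the Moore
  neighbourhood, and stencils combine linearly:
  `P = r·G + c_f·C + q·I`, followed by clipping at zero and normalisation
  *only when the total exceeds one*. The residual `1 − ΣP` is the
  probability of staying put. This matters: with only random movement
  active, `P = r·G` sums to `r`, so `r` is literally the probability of
  taking a random step. Unconditional normalisation would erase `r` and
  with it the ability to model motility inhibition by lowering `r`; the
  walker's effective diffusivity is then linear in `r`, which the test
  suite verifies (R² > 0.95 over `r ∈ {0.25, 0.5, 0.75, 1}`).
* The chemoattractant is a single effective species, produced by cells at
  rate `c₁`, degraded at occupied sites at rate `c₂`, diffusing `D` times
  faster than cells. Receptor saturation attenuates the response through
  `(1 + 3u)⁻²`. Whether the species is attractive or repulsive is carried
  by the sign of `c_f` alone.
* Proliferation is a per-step Bernoulli event (probability α); a dividing
  cell stays put and places its daughter on a free 8-neighbour. With the
  default α = 0 the mechanism is inert, reflecting the scarcity of mitoses
  within a 24 h assay. The biologically measured range,
  α ≈ 0.0007–0.001 per step, is the product of a per-step division
  probability of 0.004–0.006 (19–30 h cycle at a 7 min step) and a
  proliferative fraction of 15–20 %.

## Parameters

| Parameter | Meaning | Units | Default | Rationale |
|---|---|---|---|---|
| `D` | chemical/cell diffusivity ratio | — | 50 | calibrated optimum; gives D_chem ≈ 630 µm²/min, glucose-like |
| `c1` | attractant production | per occupied site per time unit | 0.035 | calibrated optimum |
| `c2` | attractant degradation | per time unit | `c1/2` | calibrated optimum |
| `cf` | chemotaxis strength (sign = attractant/repellent) | — | 20 | calibrated optimum |
| `q` | mechanical-interaction weight | ∈ [0,1] | 0.3 | calibrated optimum; controls early slope |
| `r` | random-step probability | ∈ [0,1] | 1 | untreated cells; lowered to model motility inhibitors |
| `alpha` | division probability per step | ∈ [0,1] | 0 | few mitoses in 24 h |
| `dt` | time step | time units | 7/1440 | one cell diameter per step; 205 steps = 24 h |
| `m` | lattice side | sites | 200 | 2,000 µm domain, borders unreachable in 24 h |
| `cellSizeUm` | site edge | µm | 10 | mean cell diameter |
| `sigmaG` | random-kernel σ | sites | 2 | near-uniform pull off the centre site |
| `neighborOrder` | mechanical range | 1 or 2 | 1 | first-neighbour forces; 2 widens the sensing window only |

Spheroid size is set per run: a diameter of 50–160 µm maps to a filled
`d × d` block of `d = 5–16` sites. The block initialiser is a square, not a
disk — at these sizes (≤ 16 sites across) the difference is a few corner
cells, and a filled square keeps the initial condition exactly
reproducible. With even `m − d` the block is exactly centred (and exactly
symmetric under quarter-turns); with odd `m − d` the corner convention
`floor((m − d)/2)` shifts it half a site, which is irrelevant at `m = 200`
but is fixed and documented rather than randomised.

## Numerical scheme

The chemoattractant PDE `∂u/∂t = D∇²u + c₁n − c₂nu` is advanced by the
explicit five-point stencil

```
U'[i,j] = (1 − 4λ)U[i,j] + λ(U[i±1,j] + U[i,j±1]) + c₁·dt·N[i,j] − c₂·dt·U[i,j]·N[i,j]
```

with `λ = D·dt/h²`. Choices worth stating:

* **Symmetric stencil.** The diffusion operator is discretised with `+λ` on
  both off-diagonals of the one-dimensional band matrix; an asymmetric
  variant (negative sub-diagonal) would implement advection, not the
  isotropic diffusion the model states.
* **Stability and positivity.** Parameter construction rejects
  `dt > h²/(2D)` (λ > ½), reporting the violated bound. Nonnegativity of
  the field additionally requires the centre coefficient at occupied sites,
  `1 − 4λ − c₂·dt`, to be nonnegative; the defaults give
  `4λ + c₂·dt ≈ 0.9722 ≤ 1`. The property test asserts exactly this joint
  bound — λ ≤ ¼ alone is not sufficient when degradation is strong.
* **Boundary.** Zero-Dirichlet: the concentration outside the lattice is
  zero, consistent with truncating the band matrix. At `m = 200` the
  spheroid never feels the boundary within 205 steps, so the choice is
  immaterial at study scale; the mass-balance test accounts for the
  boundary outflow term explicitly.
* **Gradient sampling.** The saturating concentration `u` in `(1+3u)²` is
  taken at the cell's own site (not averaged over neighbours). The
  chemotactic kernel is deliberately sparse: all mass `|μ|` sits on one
  cardinal offset, the axis with the larger gradient modulus; ties are
  broken uniformly at random. Diagonal chemotactic moves are never
  generated because gradients are only computed along the two axes.
* **Mechanical kernel.** The occupancy convolution is cropped to the 3×3
  patch around the focal cell, the cell's own contribution subtracted, the
  centre zeroed (so the kernel is a pure movement bias, like `G`), and the
  patch normalised. Forces are attractive — toward occupied neighbourhoods
  — which is what produces the pulling/pair-migration phenotype.
* **Repellents.** For `c_f < 0` the chemotactic contribution is reflected
  through the kernel centre (movement down-gradient) with weight `|c_f|`;
  clipping alone would silently disable the mechanism instead of reversing
  it.

## Update order

Cells act sequentially in a fresh uniformly shuffled order each step — a
synchronous update would need a collision-resolution rule for two cells
drawing the same target, which exclusion makes ambiguous. The chemotactic
and mechanical kernels of all cells are computed from the field and
occupancy frozen at step entry, so the shuffle order does not bias the
kernels; only the exclusion check consults the live lattice (the one
asymmetry sequential updating introduces). The field is advanced once per
iteration after all cells act; the alternative order (field first) differs
at `O(dt)` and is selectable via `fieldUpdate = "before"`. Degenerate cases
are defined, not special-cased: an all-zero composed kernel means the cell
stays with probability 1, an isolated cell has a zero mechanical kernel,
and a division with no free neighbour simply does not happen.

Every run seeds R's RNG from `params@seed` once; identical configurations
reproduce results bit-exactly, and cohorts derive per-run seeds as
`seed + index`.

## What the synthetic data does and does not show

The package never requires external data. Two generators stand in for the
microscopy pipeline:

* `brownianTracks()` emulates single cells in a low-density monolayer:
  isotropic Gaussian steps with per-axis variance `2·D·dt` (total MSD
  `4·D·dt` per step, matching the `1/(4T)` estimator's convention so
  recovery is unbiased). It emulates ideal tracking — no localisation
  noise, no track fragmentation, no field-of-view loss — so estimator tests
  certify the statistics, not robustness to segmentation artefacts.
* `runSimulation()` itself supplies spheroid-like track tables through
  `resultTracks()`, in the same µm/seconds layout as a TrackMate spots
  export.

Consequently, passing tests demonstrate internal consistency (estimators
recover generator truth; the automaton obeys its invariants; emergent
effects have the right direction and size ordering) but cannot certify
agreement with any particular experimental RRM curve — that requires real
tracked spheroids, which enter through `readTracks()`.

## Validation experiments in the test suite

The acceptance tests run the model at study scale and assert the emergent
phenomenology rather than curve-level agreement:

* size dependence — over 20 seeds at 205 steps on the 200×200 lattice,
  mean final RRM decreases across spheroid sizes `d ∈ {5, 10, 16}`
  (50, 100, 160 µm);
* chemotaxis ablation — switching chemotaxis off shifts the final RRM
  distribution significantly (two-sample KS, α = 0.05) for 160 µm spheroids
  but not for 50 µm ones: with few cells the secreted field stays too
  shallow to matter, so the mechanism's effect is an emergent function of
  colony size;
* motility inhibition — drawing `r` uniformly from 0.25–0.55 (a drug that
  reduces single-cell diffusivity to 40 ± 15 % of control) lowers the mean
  invasion velocity at every diameter;
* estimator calibration — ten independent 200-track Brownian cohorts each
  recover D = 0.21 µm²/s within 10 %, with ≥ 7/10 of the 95 % confidence
  intervals covering truth and the pooled grand mean within three pooled
  SEMs.

These sizes (20 seeds, three diameters, 200-track cohorts) were chosen as
the smallest replication at which the KS ablation contrast is decisive at
α = 0.05; the full sweep is a few minutes of computation.

## Known limitations

* The model is two-dimensional; invasion into 3-D matrix is out of scope.
* One effective chemical species: separate attractant/repellent fields, or
  spatially heterogeneous substrate stiffness, are not represented. The
  substrate enters only through the single-cell diffusion coefficient.
* Cells have no identity states (proliferative vs. migratory phenotypes
  beyond the α fraction) and never die.
* The square-block initial geometry and the square lattice impose a mild
  anisotropy on early invasion; at the 24 h horizon the RRM statistics are
  insensitive to it, but lattice artefacts would matter for shape-sensitive
  readouts.
* The sequential update is one of several defensible schemes; a synchronous
  variant would differ in detail (the `fieldUpdate` switch exposes the
  analogous ordering freedom for the field).
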