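---
title: "Coupled land-use scenarios and ecosystem services: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled land-use scenarios and ecosystem services: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landes)
```

`landes` couples two model families that are usually run as separate GIS
tools: a Markov-chain / cellular-automata (CA) land-use change simulator of
the FLUS family, and per-pixel ecosystem-service models of the InVEST
family. This vignette explains the models, their assumptions, the tunable
parameters, and the places where the design was genuinely open and we had
to choose.

## The landscape model

A landscape is a rectangular 30 m grid (row-major, north-up, cell-center
registration) of seven classes: cultivated, grass, forest, built-up,
water, shrub, unused. All layers entering a computation must be aligned —
identical shape, cell size and origin; the package refuses misaligned
inputs rather than resampling, so any reprojection must happen upstream.
Nodata propagates: a stage's output is nodata wherever any required input
is.

Areas are reported in km²; the per-cell service equations work in
hectares (one 30 m cell = 0.09 ha).

## Land-use change simulation

**Demand (Markov).** `fit_transition()` counts the empirical transition
frequencies between two observed maps; `project_demand()` applies the
matrix once to the current class areas. Both observed intervals and the
projection horizon have the same length (15 years), so a single Markov
step is exact — no annualization is needed.

**Suitability (ANN).** `fit_suitability()` trains a single-hidden-layer
neural network (via `nnet`, softmax output; multinomial logistic as the
deterministic-friendly alternative) on a uniform 10% sample of cells,
labels = current class, features = the 14 driver layers. Probabilities are
normalized per cell. The original tool's network architecture and sampling
rate are not published; `hidden = 8` and `sample_frac = 0.1` are this
package's declared defaults, chosen as the smallest settings that saturate
held-out accuracy on the synthetic fixtures.

**Allocation (CA).** `allocate_ca()` iterates a competition round. The
conversion weight of cell x toward class k is

    w(x, k) = suitability_k(x) * neighbourhood_k(x) * inertia_k * allowed(c(x), k)

where `neighbourhood_k` is the Moore-3×3 fraction of class k floored at
0.01 (so absent classes can still seed — a standard CA device that avoids
absorbing states), and `inertia_k` self-adapts each iteration as
`inertia_k * (1 + 0.1 * gap_k / demand_k)`, clipped to [0.1, 10], so
classes under demand bid higher. Winners are drawn per under-demand class
by repeated roulette wheel — weighted sampling without replacement over
w — bounded by each donor class's surplus, and at most a quarter of the
remaining gap converts per iteration (at least 25 cells) so change grows
in neighbourhood-guided clusters instead of appearing at once. Frozen
cells never change; forbidden conversions never occur; demand that is
infeasible under the constraints is reported via a warning and a
`final_gap` attribute, never silently forced. The inertia rule and step
cap are this package's own concretization of the published
"self-adaptive inertia and competition" mechanism, whose internals are
cited but not printed anywhere we could implement from.

**Validation.** `figure_of_merit()` scores a simulated map against the
observed change: FoM = hits / (misses + hits + wrong-change + false
alarms). The pipeline also reallocates the observed interval and compares
its FoM to a random-allocation baseline with the same amount and
composition of change; on synthetic regions the CA beats the baseline by
roughly an order of magnitude (about 0.1–0.15 vs about 0.01).

**Scenarios.** Three standard configurations operationalize the usual
policy narratives: BAU (raw Markov demand, no constraints), ELP (nature
reserves = the upper-elevation forest core, reservoirs = all water cells,
and basic farmland frozen; forest demand boosted ×1.15; optional
cultivated-land floor of 7% of the landscape), and RUD (built-up demand
×1.5, basic farmland frozen). The narratives give no numbers, so the
multipliers are package defaults, exposed as `scenario_config()`
arguments. Because every water cell is frozen under ELP, the default
pipeline floors water demand at its current area — otherwise the
proportional renormalization would ask a frozen class to shrink.

## Ecosystem services

* **Carbon storage**: `CS = 0.09 ha × (Ca + Cb + Cs + Cd)` per cell from
  the four per-class pool densities (Mg C/ha). A stock snapshot per map;
  scenario change is a difference of stocks (the same static assumption
  the source models make).
* **Water yield (Budyko)**: `AET/P = 1 + PET'/P − (1 + (PET'/P)^ω)^{1/ω}`
  with `PET' = Kc(class) × PET`, `Y = (1 − AET/P) P` in mm. ω is nowhere
  given in the source material; the package default is a scalar ω = 3.0
  (typical of temperate catchments), overridable per cell. Open water
  evaporates freely: `Y = max(P − PET', 0)`. Cells with P = 0 yield 0.
* **Flood regulation**: `FR = (Ymax − Y)/(Ymax − Ymin)` — a linear
  inversion of yield, so water bodies and dense forest score highest.
  When several maps are compared the extremes are taken jointly, so the
  surfaces share one scale.
* **Soil conservation**: `SC = RKLS − USLE = R·K·LS·(1 − C·P)`. The LS
  factor is not specified by the source; we use the standard USLE-family
  form `LS = (A_s/22.13)^0.5 (sin θ / 0.0896)^1.35` with `A_s` the D8
  unit contributing area capped at a 122 m slope length to bound ridge
  artifacts.
* **Water purification (nitrogen export, the one negative indicator)**:
  `λ = log Σ_upslope Y` (natural log — the base cancels in the ratio),
  `HSS = λ / mean(λ over the watershed)`, `ALV = HSS × pol × cell_ha`.
  Watersheds are the D8 basins of the filled DEM; mean HSS is exactly 1
  per watershed by construction, which the tests assert.
* **Habitat quality**: `Q = H × (1 − D)` with D a weighted sum over
  threats of distance-decayed impact × per-class sensitivity, clipped to
  [0, 1]. We deliberately clip rather than renormalize by the weight sum:
  renormalization makes quality non-monotone in the threat set (removing
  a threat would raise the remaining threats' share and could lower Q),
  which contradicts what a degradation index should do.
* **Crop production**: `PRO = Σ_districts A_i R_i P_i` per crop (grain,
  vegetable, fruit); scenario response enters by scaling each district by
  its change in cultivated cells. The per-cell CP surface (district total
  spread over its cultivated cells) exists only so crop production can
  enter the summed indicator and the correlations on the common grid;
  the tonnage is the authoritative output.

**Hydrology plumbing.** DEMs are pit-filled (Planchon–Darboux with a
10⁻⁴ m descent epsilon, so filled areas drain), routed with D8
steepest-descent (ties broken by a fixed neighbour order), and
accumulated in one pass over cells sorted by decreasing filled elevation.
Flow accumulation is tested against exhaustive path enumeration on grids
up to 20×20.

## Summed indicator and trade-offs

Each service surface is min–max standardized to [0, 1] (the negative
indicator flipped) using extremes computed jointly over all compared
maps — per-map extremes would make cross-scenario means meaningless. The
summed indicator is `SES = Σ w_i S_i` with default weights CS 0.1596,
FR 0.1688, WP 0.0875, SC 0.1396, HQ 0.1574, CP 0.0964. The weights do
not sum to 1 (they total 0.8093) and are used exactly as given;
renormalization is available but off by default.

Trade-offs and synergies are measured as pairwise correlations over 2000
uniform random sample points on the joint valid mask. Spearman is the
default (the sign is what carries the trade-off/synergy reading); Pearson
is also computed because both conventions are in circulation for this
analysis, and the pipeline stores both.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture dump. It
emulates a mountainous conservation-area landscape:

* a Gaussian-smoothed random-field DEM (autocorrelation length 8 cells,
  800 m relief) with a gentle regional tilt;
* an initial map assigned by banding a fuzzed elevation percentile so
  water sits in valley floors and forest/shrub on high ground — which
  also makes terrain genuinely informative for the suitability model;
* a later map produced by applying a known row-stochastic transition
  matrix class-wise, with per-class cell counts fixed by largest-remainder
  rounding (so realized frequencies match the ground truth almost
  exactly) and changed cells chosen by an adjacency-seeking affinity
  (distance-decay to existing patches of the target class plus smooth
  noise), so change grows from patch edges the way a neighbourhood-aware
  CA can learn;
* 14 driver layers (terrain derivatives, autocorrelated socio-economic
  and climate fields with an elevation lapse on temperature, distance
  transforms to seeded roads/rivers/settlements/stations/hazard points);
* climate, erosivity, erodibility and available-water fields, a 2×2
  district grid, and parameter tables with plausible, range-respecting
  values.

Everything is bit-reproducible under a single seed; per-stage seeds are
derived from it by hashing the stage name, so stages can be rerun in
isolation. Default extents: 100×100 cells for pipeline runs and
examples, 500×500 for the statistical recovery checks, 40×40 for the
repeated-allocation checks.

What the generator does *not* emulate: the magnitudes of any real
region's service totals, real road/river network geometry, multi-date
climate change (climate is held fixed across scenarios, as in the study
design), or sub-watershed boundaries from external hydrography. Passing
tests therefore demonstrate internal correctness and ordinal behaviour
(which scenario gains forest, which loses habitat), not calibrated
absolute predictions for any real landscape.

## Numerical choices and degenerate inputs

* Transition rows of empty classes default to identity; row sums are
  exact to 1e-9.
* A constant water-yield surface makes flood regulation degenerate; the
  package sets FR = 1 with a warning rather than dividing by zero.
* Constant rasters cannot be standardized (error), and a map with no
  observed change has no defined figure of merit (error, not 0).
* Zero-variance services at the sample points are flagged in the
  correlation output, not silently dropped.
* The CA demand tolerance is max(1 cell, 0.1% of class demand); the
  allocator converts at most `step_frac` (default 0.25) of the remaining
  gap per iteration.
* Roulette draws use the Gumbel-max construction, which is an exact
  weighted sampling without replacement and keeps the whole allocation a
  pure function of the seed.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(spec = synthetic_spec(shape = c(100, 100), seed = 1),
                       seed = 1)
run <- run_pipeline(cfg, out_dir = "landes_run")
rep <- report_run(run)
rep$ses_means
rep$areas[rep$areas$class %in% c("forest", "built_up"), ]
round(run$correlations$baseline$spearman$r, 2)
```

On this default synthetic region the ecological-protection scenario ends
with the largest forest gain and the highest summed-indicator mean, the
rapid-urban-development scenario with the largest built-up gain and the
lowest mean habitat quality, and the correlation matrix shows the
carbon–habitat synergy and the crop-production trade-off.

## Known limitations

* No reprojection or resampling; inputs must share a grid.
* Raster I/O is ESRI ASCII grid (text) only.
* Nutrient routing stops at the hydrologic sensitivity score: no
  downslope retention-efficiency decay, no subsurface nitrogen.
* Sediment delivery to streams is out of scope; soil conservation is the
  on-cell retention difference.
* The CA is a single-step allocator for equal-length intervals; it does
  not chain annual Markov steps.
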