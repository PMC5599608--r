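---
title: "Methods: from telemetry and counts to population-scaled usage maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from telemetry and counts to population-scaled usage maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model and the numerical
procedure behind every stage of `sealusage`, the meaning, unit and
default of each tuning parameter, what the synthetic-data generator
does and does not emulate, and the judgement calls made where more
than one reasonable design existed.

## 1. The estimand

For a population of central-place foraging seals on a regular grid of
600 m cells, the target is the expected number of seals at sea per
cell, with pointwise 95% intervals. The decomposition is by haul-out
*cluster* `c`:

$$ M(s) \;=\; \sum_c \bar N_c \, f \, u_c(s), $$

where `u_c` is a probability surface (sums to one over the sea cells
reachable from the cluster), `f` is the mean proportion of time spent
at sea, and `N̄_c` is the cluster population estimated from terrestrial
counts divided by the haul-out probability. Conservation is exact by
construction: the grand total of the assembled mean map equals
`Σ_c N̄_c f`.

## 2. Synthetic world generator

`genWorld()` builds a self-contained test world:

* a land/sea grid (`nrows × ncols`, default 40 × 40 at 600 m) with a
  single connected sea component and a target land fraction (0.25);
* smooth covariate fields (depth, sediment fractions closing to one,
  tidal power, spring/neap flows) generated as Gaussian random fields
  with an exponential variogram (range 5 000 m by default);
* haul-out sites on coastal land cells with true abundances summing to
  `total_population` (400), and a count survey observing a fraction of
  site-years (`survey_coverage = 0.8`).

`simulateTracks()` emulates central-place foraging tags. Each animal
owns a home haul-out; life alternates between hauled-out bouts
(geometric, mean `haul_mean_steps = 6` fixes) and trips (geometric,
mean `trip_mean_steps = 12` fixes of `interval_h = 2` hours). The
at-sea preference score of cell `s` with at-sea distance `d(s)` metres
from home is

$$ \beta_d\, d(s)/1000 + \beta_{sand}\, \mathrm{sand}(s) +
   \beta_{pow}\, \mathrm{power}(s)/1000, $$

with generative truth `β = (−0.25, 2, −0.8)`, i.e. raw-scale
coefficients `−2.5·10⁻⁴` per metre, `2` per unit sand fraction and
`−8·10⁻⁴` per watt. The first fix of every trip is drawn from the
stationary distribution `π(s) ∝ exp(score(s))` over *all* sea cells
reachable from home; subsequent fixes follow a Metropolis random walk
with a symmetric 16-neighbour proposal, which preserves `π` exactly.
The return home happens within one fix interval. Consequently every
recorded at-sea fix is marginally distributed as `exp(β'x)` — the same
family the habitat model fits — which is what makes honest parameter
recovery experiments possible.

What the generator deliberately does **not** emulate: Argos-style
location error, tag duty cycles, behavioural states beyond
trip/haul-out, tidal movement of the waterline, or temporal drift in
preference. Tracks are serially dependent within trips (the walk), so
panel-robust inference is still required.

## 3. Telemetry preparation

* `cleanseFixes()` drops animals with fewer than `min_fixes = 10`
  records and removes duplicate timestamps.
* `regulariseTrack()` linearly interpolates each track onto an anchored
  2-hour clock; gaps longer than `max_gap_h = 24` hours are left as
  segment breaks rather than bridged. A fix is flagged hauled-out when
  it brackets onshore positions.
* `segmentTrips()` cuts tracks at hauled-out fixes. Every at-sea fix is
  associated with the departure haul-out in the first half of the trip
  and the destination haul-out in the second (the *midpoint rule*).
  This is a judgement call: alternatives (nearest haul-out, departure
  only) bias distance covariates for looping trips.

## 4. At-sea distances

Distances respect land. Sea cells form a graph with 16-connectivity
(rook + diagonal + knight moves; step costs `h`, `h√2`, `h√5` for cell
size `h`), and `atseaDistance()` runs multi-source Dijkstra from the
waterline adjacent to a haul-out. Two geometric rules prevent paths
from cutting through land: a diagonal step is blocked when both of its
orthogonal intermediate cells are land (a "pinched corner"), and a
knight step is blocked when either of the two cells its
centre-to-centre segment traverses is land. The brute-force oracle in
the test suite implements the same definition independently.

## 5. Haul-out clustering

Haul-out cells (observed hauled-out fixes plus surveyed sites) are
agglomerated at every scale in `seq(600, 15000, by = 600)` metres:
two clusters merge when both their centroid distance and the minimum
at-sea distance between members fall within the scale. The resulting
clusters-vs-scale curve is monotone; `changepointScale()` fits an
at-most-one-change (AMOC) model by exhaustive single-break least
squares and returns the scale just after the break. Counts are then
attached per cluster from the most recent survey of each member cell
(ties broken by the larger count), telemetry clusters with zero counts
get a provisional one, and all counts are rescaled so the total equals
the surveyed total.

## 6. Kernel usage surfaces

Per animal, `selectBandwidth()` computes a 2-d plug-in bandwidth: the
data are pre-whitened by the symmetric square root of their
covariance, fourth-order density functionals are estimated with
Gaussian kernels at a normal-scale pilot, and the AMISE criterion is
minimised over Cholesky-parameterised bandwidth matrices
(Nelder–Mead). The selector is rotation-equivariant
(`H(XRᵀ) = R H(X) Rᵀ`) and falls back to a ridged normal-scale matrix
with a warning for degenerate point sets. `kdeSurface()` evaluates
the bivariate normal mixture at sea-cell centres, multiplies by cell
area and renormalises over sea, so every surface is a discrete
probability distribution.

Animals differ in information content: a tag alive for months
discovers more distinct cells than one alive for days. A gamma GLM of
discovered-cell count on log lifespan and tag type
(`fitWeightModel()`) supplies fitted discovery rates, and cluster
usage is the convex combination of member animals' surfaces with
weights proportional to the fitted rates (`normalisedWeights()`,
summing to one per cluster — a per-cluster choice, so an animal's
weight depends on which other animals share its cluster).

## 7. Habitat model for null clusters

Clusters without telemetry get a model-based `u_c`. The design is
use–availability: one presence row per at-sea fix, and for each
presence exactly 5 pseudo-absences drawn uniformly from the sea cells
reachable from the presence's cluster, with the distance covariate
measured from that same cluster. Pseudo-absences carry unique panel
identifiers; presences are panelled by animal.

The model is a binomial logistic GEE with independence working
correlation: point estimates equal the ordinary logistic MLE, and
panel-clustered sandwich covariance provides inference. Because only
~15 panels (animals) carry the score correlation, the plain HC0
sandwich is biased downward; `fitGee()` therefore defaults to the
Mancl–DeRouen (2001) leverage-corrected residuals
`g_p = X_pᵀ (I − H_pp)⁻¹ e_p`. In 50-replicate recovery experiments
this moved 95% CI coverage from 84–86% to 88–96%. The plain estimator
(`se_correction = "none"`) is retained and unit-tested against
`sandwich::vcovCL(type = "HC0", cadjust = FALSE)`.

Covariates are standardised internally (constants stored for
prediction); spline terms use a cubic B-spline basis with 4 df and one
interior knot at the training mean, reproduced in the tests by the de
Boor recursion. Collinearity is screened by VIF (threshold 5), and
flagged pairs may not co-enter a model.

### Cross-validation: the fold pass score

Model quality is judged by spatially blocked cross-validation.
`makeFolds()` assigns whole clusters to `k = 5` folds by greedy
bin-packing on presence counts (capped at the number of presence
clusters, with a message). For each fold, the model is fit on the
rest, held-out rows are aggregated to (cluster, cell) level (mean
predicted intensity, summed presences), sorted into 40 equal-count
bins, and tested with a one-sided Spearman rank correlation at
α = 0.05. The **fold pass score** is the number of passing folds
divided by `k`, so it takes values on the grid `0, 1/k, …, 1`. Under
the null (predictions unrelated to observations) the per-fold test
passes ~5% of the time by construction.

Forward selection starts from the base model (year + distance), offers
each candidate as linear and as spline, and admits only strict FPS
improvements. A consequence of the coarse granularity: when the base
model already scores FPS = 1 (common on the synthetic worlds, where
distance dominates), nothing can improve on it and selection keeps the
base model — which also means pure-noise candidates are almost never
selected. Prediction for a null cluster evaluates
`exp(linear predictor)` over its reachable sea with the year fixed at
the reference level (the training level nearest the median presence
year; unseen years at prediction time are mapped to the same level)
and renormalises.

## 8. Uncertainty propagation

Three variance sources enter each cluster map `N̄ f u(s)`:

* **Within-cluster usage variance** `σ²_u(s)`: for clusters with at
  least `min_animals` tagged animals, the weighted spread of member
  animals' surfaces around the cluster mean. For the rest, a
  regression fitted on the data-rich clusters predicts it:
  `log(var + ε) ~ log(mean + ε) + n_animals` (per-cell rows,
  `ε = 10⁻¹²`; null clusters use `n_animals = 0`). The full-study
  default threshold is 7 animals; the demo configuration uses 2
  because a 15-tag study rarely yields clusters with 7. At least two
  data-rich clusters are required; the animal-count term is dropped
  with a message when all data-rich clusters share one sample size.
* **Population variance** `σ²_N`: a parametric bootstrap
  (`n_boot = 10 000`) draws haul-out probabilities from a beta
  distribution moment-matched to mean 0.72, sd 0.05 (clamped to
  (0.01, 0.99); logit-normal fallback with a warning when no beta
  matches), and divides the count by each draw.
* They combine exactly for independent factors:
  `Var = f² (N̄² σ²_u + u² σ²_N + σ²_u σ²_N)`.

Intervals are normal-approximation `mean ± 1.96 sd`, truncated below
at zero — a pragmatic choice; a full bootstrap of the map would be
markedly more expensive for little change in the synthetic worlds.

## 9. Assembly, artefacts and the staged pipeline

`assembleUsage()` sums cluster means and variances cell-wise,
recomputes intervals from the combined variance, and records
provenance (share of total usage from telemetry vs model clusters).
`runPipeline()` persists three stages (`simulate`, `analyse`,
`assemble`) with a config-hash manifest: re-runs skip up-to-date
stages, deleting an intermediate re-runs it and everything
downstream, and the ESRI ASCII rasters are written with `%.17g`
precision so repeated runs are bit-identical.

## 10. Parameter reference

| parameter | default | unit / meaning |
|---|---|---|
| `interval_h` | 2 | regularisation clock (hours) |
| `max_gap_h` | 24 | longest interpolated gap (hours) |
| `min_fixes` | 10 | minimum records per animal |
| `scales` | 600–15 000 by 600 | clustering scales (m) |
| `ratio` | 5 | pseudo-absences per presence |
| `k` | 5 | cross-validation folds |
| `n_bins` | 40 | bins per fold for the Spearman test |
| `alpha` | 0.05 | per-fold significance level |
| `haulout_prob` | (0.72, 0.05) | haul-out probability mean, sd |
| `n_boot` | 10 000 | population bootstrap draws |
| `min_animals` | 7 (demo config: 2) | data-rich cluster threshold |
| `vif threshold` | 5 | collinearity screen |

## 11. Open questions and judgement calls

* **Midpoint trip association** (§3) vs nearest-haul-out: chosen for
  symmetry between outbound and inbound halves.
* **Per-cluster weight normalisation** (§6): an animal visiting two
  clusters receives a different relative weight in each; the
  alternative (global weights) would leave cluster surfaces unnormalised.
* **FPS granularity** (§7): with `k = 5` the score cannot distinguish
  models between grid points, and a base model at the ceiling freezes
  selection. A larger `k` trades this against fold stability.
* **Binned Spearman** (§7): 40 equal-count bins stabilise the rank
  test against single-cell noise; the remainder cells go to the
  leading bins deterministically.
* **Sandwich correction** (§7): Mancl–DeRouen by default; the plain
  HC0 panel sandwich remains available for comparison and for checking
  against external implementations.
* **Problem sizes** in the tests (40 × 40 worlds, 15 animals, 50
  replicates) are the package's own validation choices, balancing
  statistical resolution against runtime.
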