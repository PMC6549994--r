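---
title: "Methods: scenario-led LULC projection with MLP–Markov ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scenario-led LULC projection with MLP–Markov ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landmarkov)
```

# The procedure and its assumptions

`landmarkov` implements the five-stage land-change modelling workflow used in
applied landscape ecology to project categorical land-use/land-cover (LULC)
maps under contrasting policy scenarios: change analysis between two dated
maps, driver screening, per-origin-class transition-potential modelling,
Markov-chain change demand with scenario editing, and spatial allocation.

The core assumptions are those of every first-order Markov land-change model:

* transition propensities observed between the two calibration dates persist
  (business as usual) or are edited explicitly (scenarios) — the chain is
  time-homogeneous within the projection horizon;
* the class of a pixel at the end of the horizon depends on its current class
  (through the transition matrix) and its suitability (through the potential
  models), not on its longer history;
* driver layers either stay fixed (static: altitude, slope, soil-derived
  surfaces) or are deterministic functions of the evolving map (dynamic:
  distance to a class), recomputed per projection step.

Rasters are exchanged as ESRI ASCII grids. Grids are row-major with cell
(1,1) at the map's north-west corner; all distances and trend-surface
coordinates use pixel centres. A cell that is nodata in *any* input of a
cross-raster operation is excluded from that operation. This build reads no
GeoTIFF: nothing pre-installable in the target environment parses TIFF from
R, and the ASCII grid keeps every fixture human-readable.

# Stage by stage

## Change analysis

`cross_tabulate()` counts every ordered class pair over cells valid at both
dates; the legend's order fixes matrix row/column order throughout.
`change_budget()` converts counts to hectare gains/losses/net change and
antisymmetric pairwise contributions (`contribution(i→j) = −contribution(j→i)`,
so net changes sum to zero). `transition_mask()` builds the Boolean
change images used both for evidence likelihood and for trend mapping;
persistence is never change. `trend_surface()` fits the 0/1 change indicator
on a bivariate polynomial of pixel-centre coordinates standardized to
[−1, 1] (numerical stability of the normal equations); the default order 3
matches common trend-mapping practice in this software family.

## Drivers

*Distance variables* use an exact Euclidean distance transform (two-pass
envelope-of-parabolas algorithm, verified against brute force), not a
raster-graph approximation. Distance-to-class variables are the *dynamic*
ones: they must be recomputed whenever the map changes.

*Evidence likelihood* follows the reading "relative frequency of each
category within change areas": EL(c) = P(category = c | change), so the
values over categories sum to 1. Because the upstream tooling's manual is
ambiguous between this and P(change | category), the alternative is exposed
as `mode = "conditional"` and tested, but is not the default.

*Cramér's V* discretizes continuous variables into `n_bins = 256`
equal-interval bins (the granularity documented for the source software
family), drops empty rows/columns of the contingency table, and returns
√(χ²/(n·(min(r,c)−1))). Screening retains variables with V **strictly**
greater than the threshold (default 0.15): published screening tables
describe retained variables as V > 0.15 and dropped as V < 0.15, and
dropping at equality is the conservative completion of that rule. In the
config-driven pipeline the screening response is the date-2 class map;
association with the resulting cover is what the upstream variable-testing
tool measures, and it is the choice under which both persistent structure
and change contribute.

## Transition sub-models

One multiclass MLP per origin class, with outputs = observed destinations
plus persistence. (Published studies enumerate per-transition sub-models;
per-origin multiclass covers the same transitions with far fewer models and
identical per-transition potentials, and a per-transition binary mode can be
had by restricting the label set.)

Sampling is stratified: up to `n = 10000` pixels with equal per-label quotas
truncated to availability, each label split half into training and half into
validation (overall difference at most one pixel). Persistence pixels are
included as a label — potentials must distinguish change from no-change, and
a sample of transitions only cannot calibrate that contrast.

Architecture and training (all configurable, all logged):

| setting | default | why |
|---|---|---|
| hidden nodes | max(4, ⌈(inputs+outputs)/2⌉) | small nets suffice for smooth drivers |
| activations | sigmoid (both layers) | the classic backprop configuration |
| learning rate / momentum | 0.01 / 0.5 | documented defaults of the source software family |
| updates | shuffled mini-batches of 50 | full-batch descent at lr 0.01 stalls inside the early-stopping window |
| epochs | ≤ 10 000, early stop after 100 without validation improvement | bounded runtime |
| restarts | 3, keep best validation fit | ~10% of single inits die in the majority-class corner and never move |
| feature scaling | min–max to [0,1] from training-half statistics | keeps validation strictly out-of-sample |

Validation accuracy is the percentage of validation pixels whose arg-max
output matches their label; ≥ 75% is flagged "good", the conventional bar
for these models. `backwards_stepwise()` retrains with each variable held
out and drops the least-damaging variable while the accuracy drop stays
within `tolerance` (default 2 percentage points ≈ two binomial standard
errors of validation accuracy at the default sample sizes — i.e. "no
statistically meaningful degradation"; a tighter tolerance makes selection
hostage to training noise). The "pairs" pass (all pairwise hold-outs after
single hold-outs converge) is implemented but off by default: its one-line
description upstream under-determines it.

## Markov demand and scenarios

`estimate_matrix()` row-normalizes the counts (the maximum-likelihood chain
for the observation interval) and rescales to the horizon by the principal
fractional matrix power, computed by eigendecomposition with complex
principal logarithms; tiny negative entries are clamped and rows
renormalized. Matrices whose principal power is not real raise an error
directing the user to `rescale = "linear"`, which scales off-diagonal mass by
target/base and restores the diagonal. The choice materially affects
projections, so it is explicit and logged rather than silent.

Scenario edits operate on the 3-decimal scale of published matrices with
round-half-to-even, because that is the arithmetic that reproduces published
edited cells exactly. Donor semantics: an increased off-diagonal cell is
compensated from the diagonal; an increased diagonal from the row's largest
off-diagonal cell — the only rule consistent with both edited rows of the
published conservation matrix. Edits apply in file order; the order is part
of the scenario's identity. One known quirk is preserved rather than
resolved: applying exact donor arithmetic to the published business-as-usual
conifer row gives persistence 0.660 where the published matrix prints 0.659
(the upstream edit was evidently made on unrounded internal values); the
package reproduces the exactly reproducible cells (0.282, 0.316, 0.347) and
reports the 0.001 discrepancy. Row sums of published matrices are accepted
at ±0.005 (3-decimal rounding) and computed matrices at 10⁻⁹.

## Allocation

Greedy ranked allocation: demand in hectares is converted to whole pixels
with round-half-even; for each transition the eligible pixels are ranked by
potential, ties broken by one seeded permutation of cell indices (logged,
deterministic); a pixel claimed by several transitions goes to its highest
potential and the loser resumes down its ranking. Shortfalls are reported as
unmet demand, never silently redistributed. This is deliberately *not* the
multi-objective allocation of the upstream software — the published
description constrains outcomes, not the allocator — and the greedy rule is
reproducible and oracle-testable; the allocator sits behind its own function
so alternatives can be plugged in. Default projection is a single step over
the full horizon; multi-step mode re-derives the per-step matrix as the
horizon-th fractional power and recomputes dynamic distance layers between
steps.

# The synthetic world

`synthetic_scenario()` states a world: grid shape (default 100×100 at 25 m),
class shares, an autocorrelation length (Gaussian smoothing, sd in pixels —
quantile-thresholding the smoothed field gives exact shares up to ties), a
row-stochastic `P_true` per base interval (default 8 years, a 2007–2015
style map pair), and drivers (smooth gradient, smoothed noise, or distance
to random lines) with log-odds coefficients β. `evolve()` moves each pixel
with probabilities `P_true[i, ]` modulated multiplicatively by
plogis(Σ βz) and renormalized within each origin class, so the class-mean
transition probabilities equal `P_true` exactly *in expectation*; tests
therefore use binomial sampling-error tolerances, never equality.

What a green test establishes: the estimators recover known dynamics under
spatial autocorrelation, covariate-driven heterogeneity and nodata margins.
What it does not: classification error in real maps, legend mismatches
between products, non-stationary drivers, or any real geography's
topography — the generator emulates none of these.

One calibration lesson is recorded as a warning to users designing their own
recovery experiments. A first version of the driver-recovery world used
transition prevalence 0.15, which leaves the stratified sample
majority-persistence; the Bayes-optimal arg-max classifier then ignores
every driver, and *no* accuracy-based selection procedure can recover the
informative one — the failure is in the experimental design, not the
estimator. The shipped world uses prevalence 0.3 (both strata filled, labels
balanced) and β = 3.

# Numerical choices and degenerate inputs

* Distance transform: exact, finite-sentinel envelope algorithm (an infinite
  sentinel poisons the envelope with Inf−Inf).
* Cramér's V: constant responses are an error (V undefined); a constant
  continuous variable yields a single bin and V = 0.
* `estimate_matrix()`: a class absent at the first date is an error — its
  row has no maximum-likelihood estimate.
* Scenario edits: donor underflow (compensation exceeding the donor cell) is
  an error, not a clamp; unknown class names are errors.
* `trend_surface()`: fewer valid cells than polynomial terms is an error;
  rank-deficient fits zero the aliased coefficients.
* Every stochastic operation (sampling, training, tie-breaks, synthesis)
  requires an explicit seed; the pipeline refuses configs without one and
  echoes all seeds into the run log.

# Known limitations

* No GeoTIFF/reprojection/resampling: inputs must be co-registered ASCII
  grids.
* No zoning masks, patch-growing or cellular-automata neighbourhood effects
  in allocation.
* Discrete-time chains only; horizon rescaling by fractional power assumes
  embeddability and falls back to linear scaling when it fails.
* The MLP is one hidden layer by design; it is a potential *ranker*, and its
  validation accuracy — not calibration — is the reported diagnostic.
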