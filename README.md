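# landmarkov

Scenario-led projection of categorical land-use/land-cover (LULC) maps in R,
for landscape ecologists and land-change modellers who want a reproducible,
fully testable version of the classic MLP–Markov-chain workflow: quantify
change between two dated maps, screen driver variables, model per-pixel
transition potential, turn the observed Markov chain into (possibly
policy-edited) change demand, and allocate that demand back onto the map.

## The model

Given two co-registered categorical rasters at dates t₁ and t₂ with a shared
K-class legend, the pipeline runs in five stages:

1. **Change analysis.** Cross-tabulation of the two maps gives the transition
   count matrix N (Nᵢⱼ = pixels moving from class i to class j), from which
   gains, losses, net change, pairwise contributions and Boolean transition
   masks follow; a polynomial trend surface (default cubic) maps where change
   concentrates spatially.
2. **Drivers.** Candidate explanatory rasters are built (exact Euclidean
   distance transforms to classes; evidence likelihood EL(c) = P(category c |
   change), converting qualitative layers into continuous suitability) and
   screened by Cramér's V = √(χ² / (n·(min(r,c)−1))); variables with
   V > 0.15 are retained by default.
3. **Transition sub-models.** One single-hidden-layer MLP per origin class
   (sigmoid activations, mini-batch backprop with momentum, early stopping,
   random restarts) is trained on a stratified sample of up to 10 000 pixels
   — half training, half validation — with optional backwards stepwise
   variable selection; it yields per-pixel transition potentials in [0, 1].
4. **Change demand.** The observed chain P̂ = row-normalized N is rescaled to
   the projection horizon by the principal fractional matrix power
   P̂^(T/base), then optionally transformed by declarative scenario edits
   (scale a cell, scale a diagonal, pin a row to identity — each compensated
   from a donor cell so rows stay stochastic). Demand is D = diag(a)·P with a
   the baseline class areas.
5. **Allocation.** For every demanded transition i→j, the top-Dᵢⱼ eligible
   pixels by potential change class; a pixel contested by several transitions
   goes to its highest potential. Multi-step projection recomputes dynamic
   (distance-to-class) drivers between steps.

A synthetic-landscape module generates autocorrelated class maps, covariate
drivers and two-date change under a *known* transition matrix and driver
effects, so every stage is tested against ground truth — no external data
needed.

## Worked example

Reconstructing a published ecosystem-conservation scenario from its
business-as-usual matrix and three rules (conifer→broadleaf conversion +50%,
mountain/heath/bog persistence +50%, broadleaf never converts):

```r
library(landmarkov)
bau <- wales_transition_matrix("bau")
ec  <- apply_scenario(bau, wales_ec_scenario())
ec$P["conifer forest", "broadleaf forest"]   # 0.282  (published: 0.282)
ec$P["mountain heath and bog", "mountain heath and bog"]  # 0.316
ec$P["mountain heath and bog", "semi-natural grassland"]  # 0.347
screen_variables(wales_screening_table())
#> Screening at V > 0.15: 14 retained, 6 dropped
```

An end-to-end run on a synthetic landscape with known dynamics:

```r
spec <- synthetic_scenario(
  seed = 7, shape = c(100, 100), shares = c(0.4, 0.3, 0.3),
  P_true = matrix(c(0.85, 0.10, 0.05,
                    0.05, 0.90, 0.05,
                    0.05, 0.10, 0.85), 3, byrow = TRUE),
  drivers = list(list(name = "alt", type = "smooth-gradient", beta = 1.5)))
g  <- generate_t1(spec)                 # date-1 map + driver rasters
t2 <- evolve(g, spec)                   # date-2 map under P_true
counts <- cross_tabulate(g$map, t2)
estimate_matrix(counts, base_years = 8, target_years = 15)
#> TransitionProbabilityMatrix: 3 classes, horizon 15 years
#>         class_1 class_2 class_3
#> class_1   0.741   0.167   0.092
#> class_2   0.089   0.828   0.083
#> class_3   0.091   0.170   0.739
change_budget(counts)
#>     class gains_ha losses_ha   net_ha
#> 1 class_1  19.7500   38.0000 -18.2500
#> 2 class_2  43.0000   18.8125  24.1875
#> 3 class_3  22.6875   28.6250  -5.9375
```

The estimated 8-year chain sits within binomial sampling error of `P_true`,
then compounds to the 15-year horizon (diagonals shrink, off-diagonals grow).
The change budget is in hectares (100×100 grid of 25 m pixels = 625 ha
total); net changes sum to zero because change moves area, never creates it.

The full workflow — including MLP training, scenario files and projection —
runs from one INI-style config via `run_pipeline(config, out_dir)` or the CLI
wrapper (`Rscript inst/cli/landmarkov.R run --config study.conf --out out/`);
see the methods vignette (`vignettes/landmarkov-methods.Rmd`).

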