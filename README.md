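# maxsdm

Presence-background species distribution modelling (SDM) with a
maximum-entropy model restricted to **linear and quadratic features**, the
combinatorial bioclimatic-variable selection used in range-shift studies of
relict trees, **consensus ("refined") uncertainty maps**, multi-scenario
climate projection, and km²-scale range accounting — all runnable end to end
on simulated landscapes, with no raster downloads.

It is aimed at ecologists who model restricted-range species (the motivating
case is the dove tree *Davidia involucrata*, a Tertiary relict of the
mountains around the Sichuan Basin) and want the full analysis chain —
variable selection through protected-area accounting — as tested, scriptable
R functions rather than a GUI workflow.

## The model

For presence cells \(x_1,\dots,x_n\) and a background sample of \(m\) cells,
the fitted distribution is the Gibbs density over background cells

```
q(x) = exp(η·f(x)) / Z,
```

where `f(x)` stacks, per climate variable, the min–max scaled value and its
square (so every feature lies in [0, 1] on the training data).  The
coefficients η minimize the L1-penalized convex objective

```
J(η) = −(1/n) Σᵢ η·f(xᵢ) + log Σ_bg exp(η·f(x)) + Σⱼ βⱼ|ηⱼ|,
```

solved by a proximal-Newton iteration with coordinate descent on the
penalized quadratic model (KKT tolerance 1e-6).  Suitability on the 0–1
scale is the logistic output `p = e^H q / (1 + e^H q)` with `H` the entropy
of `q` over the background, so a no-signal model scores exactly 0.5.

Around the fit, the package provides:

* **Variable selection** — Pearson correlation grouping at `|r| ≥ 0.85`
  (connected components), exhaustive candidate subsets with ≤ 2 variables
  per collinear group, VIF > 10 exclusion, and AICc ranking with the
  likelihood normalized over all valid study-area cells.
* **Evaluation** — k-fold (default 20) cross-validation, rank-based AUC,
  and the maximum sensitivity + specificity (MSS) threshold.
* **Consensus refinement** — the k binary fold maps are summed into an
  agreement map; pixels predicted suitable by fewer than 95 % of the models
  (19 of 20) are removed from the averaged map.
* **Projection and accounting** — clamped projection onto scenario stacks,
  suitability bands (threshold–0.5, 0.5–1), spherical-geometry km² areas,
  gains/losses/overlaps between scenarios, and protected-area coverage.
* **A virtual-species simulator** — smooth correlated climate surfaces with
  exact target correlations, a known Gaussian niche, occurrence sampling
  with per-pixel duplicates, scenario shifts, and protected-area masks.

## Worked example

```r
library(maxsdm)

w   <- synthetic_world(seed = 1)              # 150x150 landscape, 8 variables
cfg <- sdm_config(background_n = 2000, k_folds = 20, seed = 1)
res <- run_pipeline(w$stack, w$occurrences,
                    scenarios = w$scenarios["warming2070"],
                    protected_mask = w$protected_mask, config = cfg)
res
#> <sdm_pipeline>
#>   variables: v1, v2
#>   CV AUC = 0.945 +/- 0.014, threshold = 0.2065
#>   scenarios: present, warming2070

subset(res$table, select = c(model, total_km2, high_fraction_pct, diff_pct))
#>                 model total_km2 high_fraction_pct  diff_pct
#> 1             present  68725.80          35.41273        NA
#> 2         warming2070  36848.63          34.66711 -46.38312
#> 3 average warming2070  36848.63          34.66711 -46.38312

res$protection
#>         model inside_km2 outside_km2 total_km2 pct_outside
#> 1     present  20269.061    48456.74  68725.80    70.50735
#> 2 warming2070   5884.401    30964.23  36848.63    84.03088
```

The niche truly drives `v1` and `v2`; selection recovers exactly that subset
from 247 candidates.  The cross-validated AUC (0.945) says held-out
presences outrank background cells 94 % of the time.  The table reports,
per scenario, the refined (≥ 95 % consensus) suitable area in km², the share
of it in the high-probability band (≥ 0.5), and the signed change relative
to the present: the +1.5 SD warming shift contracts the projected range by
46 %, and the share of suitable habitat outside the protected-area mask
rises from 71 % to 84 %.

A published range-accounting table for the dove tree ships with the package
(`davidia_range_table()`); `scenario_table()` reproduces every derived
percentage and period average in it from the printed km² inputs.

## Not in scope

Downloading WorldClim/GBIF data, reprojection between CRSs (only regular
lon/lat grids), GeoTIFF I/O (grids are read/written as ESRI ASCII), and
hinge/product/threshold features.
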