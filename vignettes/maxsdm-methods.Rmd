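---
title: "Consensus-refined maximum-entropy SDM: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-refined maximum-entropy SDM: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxsdm)
```

## The problem

Restricted-range plants — the motivating case is the dove tree *Davidia
involucrata*, a Tertiary relict confined to the humid mountains around the
Sichuan Basin — are routinely assessed by presence-only species distribution
models: occurrence records plus gridded bioclimatic variables yield a
habitat-suitability surface, which is thresholded, projected onto past and
future climates, and turned into km² range accounting that conservation
planning can use.  `maxsdm` implements that entire chain as plain R
functions, and pairs it with a virtual-species simulator so every stage can
be validated against a known truth without downloading any rasters.

## The maximum-entropy model

Given presence cells $x_1,\dots,x_n$ and a background sample of $m$ cells,
the model is the Gibbs distribution over background cells

$$q(x) = \frac{e^{\eta \cdot f(x)}}{Z}, \qquad
Z = \sum_{\text{background}} e^{\eta \cdot f(x)},$$

with the feature map deliberately restricted to **linear and quadratic**
terms: per variable $v$, $f_v = (x_v - \min_v)/(\max_v - \min_v)$ and
$f_v^2$, bounds taken over the training stack's valid cells.  Restricting
the feature class keeps the response curves unimodal-or-monotone and avoids
the extrapolation pathologies of hinge/threshold features when the model is
transferred to non-analogue climates.  The quadratic feature is the square
of the *scaled* linear feature, which keeps all features in $[0,1]$ on the
training data.

$\eta$ minimizes the L1-penalized convex objective

$$J(\eta) = -\frac1n \sum_i \eta \cdot f(x_i)
          + \log \sum_{\text{bg}} e^{\eta \cdot f(x)}
          + \sum_j \beta_j |\eta_j|.$$

Presence cells are appended to the background by default (the target-group
convention of presence-background maxent software); `include_presence =
FALSE` disables it.

**Regularization.**  Each feature's penalty is
$\beta_j = \texttt{beta\_multiplier} \cdot b(n) \cdot s_j / \sqrt n$, where
$s_j$ is the feature's standard deviation over the presence sample and
$b(n)$ is the base weight of the linear+quadratic feature class,
interpolated over sample size from $(n, b)$ knots
$(10, 0.22), (17, 0.18), (30, 0.14), (100, 0.05)$ and held constant outside
— the convention established for this feature class.  A floor of $10^{-4}$
on $s_j$ keeps features that are constant across presences from becoming
penalty-free.  `beta_multiplier` (default 1) scales the whole schedule.

**Solver.**  A proximal-Newton iteration: the smooth part is replaced by
its local quadratic model (gradient $F^\top q - \bar f$, Hessian
$F^\top(\operatorname{diag} q - qq^\top)F$ with a $10^{-9}$ ridge), the
L1-penalized quadratic is solved exactly by coordinate descent with
soft-thresholding (compiled), and a backtracking line search enforces
monotone decrease of the true objective — the trace is stored and tested.
Convergence is the L1 subgradient condition within $10^{-6}$; on tiny
instances the solution is verified against dense grid search to $10^{-3}$.

**Outputs.**  Raw output is $q$ itself (sums to 1 over the training
background).  The 0–1 suitability scale is the logistic transform
$p = e^H q / (1 + e^H q)$ with $H$ the entropy of $q$ over the background,
so a no-signal model yields exactly $p = 0.5$ everywhere.  Models
serialize to a plain-text lambdas file that round-trips at full double
precision.

## Variable selection

The selection chain mirrors standard practice for the 19 bioclim variables:

1. **Correlation grouping.**  Pearson correlations are computed on the
   pooled presence + background values; variables joined by $|r| \ge 0.85$
   are grouped.  "Grouped" is read as *connected components* of the
   threshold graph — deterministic and order-free, unlike maximal cliques,
   which are ambiguous for chains like $a\sim b\sim c$ with $a\not\sim c$.
2. **Candidate enumeration.**  All subsets with at most 2 members of any
   group.  A minimum subset size of 2 is imposed: a single-variable SDM is
   degenerate for range mapping.  Both caps are arguments.
3. **VIF screen.**  $\mathrm{VIF}_j = 1/(1-R_j^2)$ from least-squares
   regressions within the subset, on the same pooled sample; subsets with
   any VIF > 10 are dropped.  Perfect collinearity reports `Inf` and fails
   the screen rather than erroring, so enumeration can continue.
4. **AICc ranking.**  Each surviving subset is fitted on the full
   occurrence set, and scored by
   $\mathrm{AICc} = 2k - 2\ln L + 2k(k+1)/(n-k-1)$ with $\ln L$ the
   log-likelihood of the occurrences under the raw distribution
   *normalized over all valid study-area cells* and $k$ the count of
   nonzero coefficients after L1 fitting — the established convention for
   information-criterion scoring of maxent models.  Ties break by smaller
   $k$, then lexicographic subset label.  Selection happens before
   cross-validation, matching the analysis sequence the chain emulates.

## Cross-validation and consensus refinement

The winning subset is evaluated by k-fold cross-validation (default
$k = 20$): each fold's model is trained on the other $k-1$ bins against the
*shared* background (background is not re-sampled per fold), and scored by
rank-based AUC of its held-out presences versus the background.  Each
fold's MSS threshold — the cutoff maximizing sensitivity + specificity
under the inclusive rule `score >= tau`, ties to the smallest cutoff — is
computed on that fold's *training* presences versus the background: the
held-out bins are reserved for AUC, and a threshold from ~10 test points
would be far noisier.  The "standard" map is the pixelwise mean of the k
logistic maps; its display threshold is the mean of the k fold thresholds
(whether a published single threshold is an average of per-run thresholds
or the MSS of the averaged map is generally unstated; both are computable
here, the average-of-thresholds is the default).

Uncertainty is handled by consensus: each fold map is binarized at its own
threshold, the k binary maps are summed into an **agreement map** (counts
0–k, equivalently 0–100 %), and pixels with agreement below 95 % — fewer
than $\lceil 0.95k \rceil = 19$ of 20 models — are removed from the
standard map, giving the **refined** map.  Refinement is monotone (raising
the consensus level never adds area) and, on synthetic landscapes, the area
it removes is concentrated in the low-suitability band, which is exactly
the behaviour that motivates it.

## Projection and range accounting

Fold models are projected onto scenario stacks using the *training* feature
bounds, with scaled features clamped to $[0,1]$ by default (the clamped
cell fraction is reported); the same binarize–agree–refine treatment is
applied per scenario.  Cell areas use a spherical Earth ($R = 6371$ km) and
the closed-form band formula
$R^2\,\Delta\lambda\,(\sin\varphi_t - \sin\varphi_b)$ — reproducible, and
verified to conserve the sphere's $4\pi R^2$; published tables computed in
GIS software under unstated projections can therefore differ slightly in
absolute km².

Accounting splits suitable area at 0.5 into a low band $[\tau, 0.5)$ and a
high band $[0.5, 1]$ (the boundary belongs to the high band), intersects
binary maps for overlap/gain/loss, and reports protected-area coverage
against a rasterized mask.  Period-average rows report percentage columns
in **both** conventions — mean of per-scenario percentages and percentage
of mean areas — because published tables mix the two (the bundled dove-tree
table's averages are means of percentages, while its abstract-level 29.2 %
figure is a ratio of means); `scenario_table()` surfaces both so the
discrepancy is visible rather than silent.

## The synthetic-data generator

`generate_landscape()` draws independent smooth base fields from a random
low-frequency cosine basis, centres and QR-orthonormalizes them, and mixes
them through the Cholesky factor of the target correlation matrix — so the
sample correlations over cells equal the targets *exactly* while each field
stays spatially smooth.  The default landscape is 150×150 cells at 2.5
arc-min over the south-central China window, 8 standardized variables, one
collinear pair at $r = 0.95$ (to exercise grouping and VIF) and two mild
correlations.

The virtual species follows a Gaussian response on `v1` and `v2` with
$\mu = 0$, $\sigma = 0.25$ landscape SD units — a narrow climatic envelope
appropriate for a montane relict; its high-suitability range covers a few
percent of the landscape.  Occurrences (default 250 raw draws) are sampled
with probability proportional to suitability, *with replacement*, matching
the presence-only sampling model maxent assumes and producing the
within-pixel duplicates that the dedup step must handle.  Scenario stacks
are additive per-variable shifts (default: a mild cool shift for the
mid-Holocene, a stronger one for the glacial maximum, and a +1.5 SD warming
future); because the niche optimum sits at the landscape mean, a warming
shift moves it into the tail of the `v1` distribution and the true range
contracts — a closed-form fact the projection logic is tested against.
Protected-area masks are grown as random contiguous patches to a requested
coverage.

What the simulator does **not** emulate: real GCM spatial patterns,
WorldClim's variable scales and units, sampling bias in herbarium records,
and non-climatic range limits (dispersal, soils, biotic interactions).
Passing recovery tests therefore shows the machinery is correct and
identifiable under its own assumptions — not that any real-data prediction
is right.

## Validation harness and problem sizes

`recovery_experiment()` runs the full chain on 20 independent worlds and
scores: true drivers contained in the selected subset, cross-validated AUC
≥ 0.9, Jaccard overlap ≥ 0.6 between the refined present-day binary map and
the true range (truth binarized at its own MSS threshold), and contraction
of the projected area under the warming scenario.  Default replicate sizes
— 150×150 grid, 8 variables (247 candidate subsets), 250 raw occurrences,
2 000 background cells, 20 folds — were chosen so one replicate carries a
realistic signal-to-noise ratio while the 20-replicate experiment completes
in a few minutes; unit tests use a 60×60, 5-variable world.

## Numerical choices and degenerate inputs

* Snapping: cell-centre registration, row 1 northernmost, half-open cell
  intervals; a point on a shared edge belongs to the cell south/east of it.
  One rule, no ambiguity at edges.
* Dedup keeps the first record per pixel in file order (determinism).
* Constant variables raise a degenerate-feature error at feature building;
  zero-variance variables are named in the correlation error.
* Exact collinearity in a VIF screen is a failed screen, not an exception.
* `NA` (nodata) propagates: every analysis is restricted to the
  conjunction of the layers' validity masks.
* Binarization is inclusive (`>= tau`) so the threshold-attaining score is
  itself "present"; the high band owns 0.5 for the same reason.
* Fold sizes differ by at most 1; 203 records in 20 folds gives 17 folds
  of 10 and 3 of 11.

## Known limitations

* Only regular lon/lat grids; no reprojection, no GeoTIFF I/O (ESRI ASCII
  only).
* Only linear + quadratic features; no sampling-bias grids.
* Exhaustive subset enumeration is exponential in the number of variables;
  practical up to ~19 variables with grouping constraints, by design.
* Absolute km² figures depend on the area model (spherical here); compare
  ratios, not absolute areas, against GIS-derived tables.
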