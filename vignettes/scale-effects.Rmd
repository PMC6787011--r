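---
title: "Modeling interactive scale effects in presence-background SDMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling interactive scale effects in presence-background SDMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Species distribution models are sensitive to two choices that are usually
made implicitly: the **total extent** of the area within which a model is
trained and evaluated, and the **grain** (cell size) of the environmental
rasters. `scalesdm` implements a complete, testable pipeline for studying
how these two axes of spatial scale interact: synthetic landscapes with a
known habitat truth, nested extent replication, factor-2 grain ladders, a
from-scratch maximum-entropy presence-background model, and accuracy,
importance, and parsimony summaries across the full factorial design.

This vignette records the modeling choices, their assumptions, and the
numerical conventions, in enough detail that a maintainer can reconstruct
every decision.

## The core model

Presence-background ("presence-only") data consist of locations where the
species was recorded, contrasted against a sample of available cells rather
than true absences. `scalesdm` fits the standard maximum-entropy (MaxEnt)
estimator for such data: a Gibbs distribution over landscape cells

$$
p_\beta(x) \;=\; \frac{\exp\{\beta^\top f(x)\}}{\sum_{j \in \text{background}} \exp\{\beta^\top f(x_j)\}},
$$

with coefficients chosen to maximize the L1-penalized log likelihood

$$
\ell(\beta) \;=\; \sum_{i \in \text{presence}} \beta^\top f(x_i)
\;-\; n_p \log \sum_{j \in \text{background}} \exp\{\beta^\top f(x_j)\}
\;-\; \sum_k \lambda_k |\beta_k|.
$$

This objective is the documented core of the MaxEnt software and is
equivalent to an inhomogeneous Poisson point-process likelihood on the
discretized landscape, so the package's fitter is a transparent,
mathematically explicit replacement for the black-box program. The tests
verify the fitter against direct numerical maximization of the identical
objective (with the L1 term handled exactly through a
$\beta = \beta^+ - \beta^-$ splitting under box constraints).

Key choices:

* **Features.** Variables are standardized to training mean/sd, then
  expanded. The default classes are linear and quadratic; product and hinge
  features (forward/reverse hinges at training-quantile knots) are
  available but off by default. Collinear expanded features are pruned by
  pivoted QR before fitting; predictors constant across the pooled training
  rows are dropped with a warning.
* **Regularization.** $\lambda_k = \lambda_0 \cdot \mathrm{sd}(f_k)$ with
  default $\lambda_0 = 0.05\sqrt{\ln n_p}$ — a mild penalty that grows
  slowly with presence count. The per-feature scaling makes the penalty
  invariant to affine rescaling of the input variables; tests confirm that
  raw predictions are unchanged (to 1e-8) when a predictor is rescaled, and
  that increasing $\lambda_0$ never increases the number of nonzero
  coefficients.
* **Optimizer.** Accelerated proximal gradient (FISTA) with backtracking
  line search and soft-threshold proximal steps; momentum restarts on any
  objective increase so the iteration is monotone. It stops when the
  objective improves by less than 1e-8 (relative) or after 500 iterations;
  both the iteration count and the converged flag are kept in the model
  object.
* **Output scales.** `raw` is the Gibbs density itself (sums to 1 over the
  training background). `cloglog`, the default display scale, is
  $1 - \exp(-e^{H} \cdot \text{raw})$ with $H$ the entropy of the training
  background distribution — a bounded (0,1) suitability. Both scales are
  monotone transforms of the linear predictor, so rank-based metrics (AUC)
  and threshold-swept metrics (max TSS) are identical between them; only
  the numeric value of the optimal threshold depends on the scale.

### Model selection and importance

* **AICc.** For presence-only models the package uses the
  normalized-likelihood convention: the raw density is renormalized over
  the supplied background cells, $LL = \sum_i \log p(x_i)$ over presences,
  $K$ is the number of nonzero coefficients, and
  $\mathrm{AICc} = 2K - 2LL + 2K(K+1)/(n-K-1)$. When $n \le K + 1$ the
  correction is undefined and `NA` is returned as an explicit
  not-computable marker; downstream parsimony tables count such replicates
  in an exclusion column instead of silently dropping them. AICc is only
  compared between variable sets at the same extent and grain — changing
  either changes the sample, which makes the criterion incomparable.
* **Permutation importance.** Each variable's values are permuted jointly
  across the pooled training presence and background rows; the drop in
  training AUC (floored at zero) is recorded and the drops are normalized
  to percentages. A full column permutation is used. When every drop is
  zero (a fully uninformative model) equal shares are reported so the
  percentages still sum to 100.
* **Response curves** sweep one variable across its observed training range
  with the other variables held at training means, on the cloglog scale.

## Evaluation metrics

* **AUC** is computed in Mann-Whitney rank form with mid-rank tie
  correction — exactly equal to exhaustive pair counting, and invariant
  under strictly increasing transforms of the predictions.
* **max TSS** sweeps every unique predicted value as a candidate threshold,
  with sensitivity the fraction of presences predicted at or above the
  threshold and specificity the fraction of background below it. The exact
  optimum over this candidate set is the global optimum; on ties the
  smallest maximizing threshold is returned, which makes the result
  deterministic. TSS was chosen as the headline accuracy metric because it
  is independent of prevalence, which varies by orders of magnitude across
  the extent-grain design.
* **Correlation** is point-biserial: Pearson correlation between pooled
  predictions and the presence/background label.
* Fold averaging is metric-wise (the five fold values are averaged); the
  threshold is never re-optimized on pooled folds.

## The synthetic landscape generator

Because the survey data that motivated this design are confidential, the
package ships a generator whose defaults emulate the structure of a
mountainous survey region at desk scale, with a known truth so that
parameter recovery is checkable:

* **Random fields.** Stationary Gaussian fields with exponential
  autocovariance are synthesized spectrally on the torus (white noise
  convolved with a kernel whose power spectrum matches the target
  covariance). `range_m` is the practical range: correlation has decayed to
  about 0.05 at that lag. The default 3000 m range gives landscape
  structure at the scale of a few survey blocks.
* **Predictors.** Elevation is a broad field plus a 900 m south-to-north
  trend around a 2400 m base (so a 3600 m alpine ceiling excludes a
  realistic fraction of cells); slope is derived from that surface with
  Horn's 3x3 stencil; percent forest is a logistic transform of a second
  field scaled to [0, 100]; roads and streams are random polylines turned
  into exact Euclidean distance rasters; 11 phenology bands are linear
  mixtures of 3 latent fields plus small-scale noise, with two mixture rows
  duplicated so that several band pairs correlate above 0.9 (the situation
  that motivates reducing them to at most five principal components
  explaining 99% of the variance); 5 climate bands are generated at 960 m
  and bilinearly resampled down, with mean temperature following a 6.5
  degC/km lapse rate on the coarse elevation.
* **Truth.** Suitability is
  $\mathrm{invlogit}(\alpha_r + \sum_v a_{r,v} z_v + b_{r,v} z_v^2)$ on
  standardized predictors, with coefficients per region. Regions are
  vertical halves or quadrants — deliberately simple geometry that is
  sufficient to express nonstationary responses (locally adapted
  populations) and trivial to verify.
* **Survey.** The landscape is tiled by square survey cells (default
  1414 m, approximating 2 km^2 survey blocks); detections per cell are
  Poisson with mean `detection_scale` times the cell's mean suitability and
  are placed uniformly within the cell. The default `detection_scale = 5`
  was chosen once so that the default landscape yields survey-scale counts:
  on the order of 30 presence cells and prevalence of order 5e-4 per 50 km^2
  block at the 30 m grain, hundreds of points per 500 km^2, and roughly a
  thousand points range-wide.

What the generator does **not** emulate: drainage-network topography,
anisotropy, bamboo understory dynamics, observer bias along transects, and
spatially structured detection failure. Passing tests on this generator
therefore demonstrate correctness of the pipeline and qualitative
reproduction of scale effects, not calibrated accuracy on real survey data.

A note on the detection model: because detections are placed uniformly
within a survey cell, the association between a 30 m presence cell and its
local environment is diluted when the survey cell is much larger than the
autocorrelation range of the landscape. This is a realistic property of
sign surveys (a sign is evidence about the neighborhood, not the exact
cell). Consequently the parameter-recovery checks use a fine survey grid
(90 m cells), strong responses, and a rare-habitat truth (intercept -3.5,
as implied by the very low observed prevalences); under those conditions
the fitted signs recover reliably and held-out AUC exceeds 0.8.

## Study design

* **Level-1 blocks** tile the domain with 50 km^2 squares anchored at the
  top-left corner; blocks with at least 20 presence points are retained.
* **Level-2 buffers** expand randomly chosen blocks to concentric 500 km^2
  squares, clipped to the domain, accepted only if disjoint from previously
  accepted buffers. Squares (rather than an unspecified buffer shape) keep
  the area bookkeeping exact. A clipped buffer records its actual area.
* **Level 3** corresponds to the truth regions of the generator (the
  synthetic analogue of mountain ranges); **level 4** is the full domain.
* **Background**: up to 10,000 cells sampled without replacement from the
  valid cells of the extent below the 3600 m elevation ceiling; when fewer
  eligible cells exist (small extents at coarse grains), all of them are
  used. Background points are cell centers, so value extraction is
  unambiguous at every grain, and presence cells are not excluded from the
  background pool (the MaxEnt background convention).
* **Folds**: a true 5-fold partition of presence cells (each tests exactly
  once), the stricter reading of "five random 80/20 combinations"; the
  background sample is shared across folds because only presences are
  partitioned. Fold and background seeds derive from the master seed per
  (replicate, grain) — not per variable set — so AICc comparisons between
  variable sets are paired on identical data.

## Raster engine conventions

* Grids are plain matrices with a top-left anchor, square cells in planar
  meters, and half-open cell membership (`col = floor((x - x0)/cell) + 1`,
  `row = floor((y0 - y)/cell) + 1`). All nodata handling is via `NA`.
* **Aggregation** by an integer factor takes the block mean (or median)
  over valid cells; trailing rows/columns that do not fill a block are
  dropped, which keeps block statistics unbiased; all-nodata blocks become
  nodata. Mean aggregation preserves the global mean exactly on full-block
  rasters and composes (factor 2 twice equals factor 4), which the grain
  ladder exploits.
* **Bilinear resampling** interpolates output cell centers from the four
  surrounding input centers, clamping to the nearest valid row/column at
  the edges, renormalizing weights over valid neighbors; the output
  dimension is `round(extent / target_cell)` so the footprint is preserved
  to within one cell (the 250 m to 240 m case).
* **Distance rasters** are exact Euclidean center-to-segment distances (no
  rasterized approximation); a cell whose center lies on the feature is 0.
* **Phenology PCA** is correlation-matrix PCA (center + unit variance),
  because the metrics mix units; computed at the 240 m rung of the ladder,
  the grain at which those bands become available, and the resulting
  components are aggregated onward to coarser grains. Distance and base
  variables are computed once at 30 m and aggregated, never recomputed per
  grain.

## Determinism

Every stochastic step takes an explicit seed, executed under
`withr::with_seed` so the caller's RNG state is untouched. The factorial
driver derives one child seed per design cell from the master seed by an
FNV-style integer hash (kept below 2^31), so adding design cells never
perturbs existing ones and two runs with the same configuration produce
byte-identical result files (numeric columns are written with 15
significant digits).

## Problem sizes used in the checks

The shipped checks run the full pipeline at desk scale, chosen so each
property is measured on the smallest design that still exercises it: the
default 1000 x 1000-cell (30 x 30 km) landscape for the grain-effect,
bookkeeping, and parsimony properties (16 level-1 replicates, five folds,
10,000 background cells); 250 x 250 landscapes over 20 seeds for parameter
recovery; 200 x 200 four-region landscapes over 20 seeds for the
nonstationarity contrast; and at most 50-cell discrete landscapes for the
fit-vs-oracle equivalence.

## Known limitations

* Extents are axis-aligned rectangles; irregular polygons (true mountain
  ranges, reserve boundaries) are out of scope, and the rectangular
  stand-in is not claimed equivalent.
* All coordinates are planar meters; no projections or geodesy.
* The fitter omits MaxEnt's threshold/category features and clamping;
  values outside the training range are evaluated as-is.
* Statistical contrasts across the design are reported as replicate-level
  summaries (means and SDs), not formal hypothesis tests.
* The IPP view suggests modeling within-cell point counts rather than
  binary presence cells; the pipeline records counts but models the binary
  mask, matching the convention under study.
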