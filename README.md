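# scalesdm

Species distribution models (SDMs) depend on two spatial-scale choices that
are usually made implicitly: the **total extent** of the study area and the
**grain** (cell size) of the environmental rasters. Changing either one
changes the presence data (nearby points merge into single cells as grain
coarsens), the predictor distributions, and ultimately model accuracy —
and the two axes interact. `scalesdm` is an R package for studying these
interactive scale effects with a fully reproducible pipeline, built for
spatial ecologists and methodologists who want scale sensitivity analysis
to be a first-class, tested part of their modeling workflow rather than a
one-off script.

The package provides:

* a lightweight planar **raster engine**: factor-2 mean/median aggregation,
  bilinear resampling, Horn slope, exact Euclidean distance-to-feature
  rasters, presence rasterization with prevalence bookkeeping, PCA band
  reduction, and ESRI ASCII grid I/O;
* a **synthetic landscape generator** with known habitat truth
  (autocorrelated Gaussian-field predictors, region-partitioned and
  optionally nonstationary responses, transect-style Poisson sign surveys),
  so every downstream stage can be validated against a ground truth;
* **study design** tools: gridding a domain into small extent replicates
  with a minimum-presence filter, buffering them into non-overlapping
  larger extents, elevation-masked background sampling, and k-fold
  presence splits;
* a from-scratch **maximum-entropy presence-background model** — the Gibbs
  / inhomogeneous-Poisson estimator with L1 regularization,
  $\max_\beta \sum_{i \in \text{pres}} \beta^\top f(x_i) - n_p \log
  \sum_{j \in \text{bg}} \exp\{\beta^\top f(x_j)\} - \sum_k \lambda_k
  |\beta_k|$ — with cloglog output, permutation importance, response
  curves, and presence-only AICc;
* **evaluation**: rank-based AUC, threshold-optimized maximum TSS (the
  True Skill Statistic, prevalence-independent), point-biserial
  correlation, fold averaging, and cross-extent transfer evaluation on
  identical test data;
* an **experiment driver** that runs the full extent x grain x variable-set
  factorial deterministically from a single master seed and emits tidy
  result, importance, gradient, and parsimony tables, plus a thin CLI
  (`inst/scripts/scalesdm.R`).

## Worked example

Generate the default synthetic world (a 30 x 30 km landscape of 30 m
cells with elevation, slope, percent forest, distance-to-road/stream, 11
correlated phenology bands, and 5 coarse climate bands), survey it, and
compare model accuracy at the finest and coarsest grain in the smallest
extent size:

```r
library(scalesdm)

cfg  <- truth_config(seed = 7)            # 1000 x 1000 cells at 30 m
land <- make_landscape(cfg)
suit <- true_suitability(land)
pts  <- simulate_survey(suit, survey_design(seed = 7))
nrow(pts)
#> [1] 925

dom    <- raster_extent(land$stack$layers$elevation)
blocks <- grid_blocks(dom, pts, block_area_km2 = 50, min_presence = 20)
length(blocks)
#> [1] 16

cfg_run <- experiment_config(grains = c(30, 1920), varsets = "base",
                             k = 5, n_background = 10000, master_seed = 7)
run <- run_factorial(land, blocks, pts, cfg_run)
s <- summarize_replicates(run$results)
s[, c("grain_m", "n_replicates", "n_presence_cells_mean",
      "prevalence_mean", "tss_max_mean", "tss_max_sd", "auc_mean")]
#>   grain_m n_replicates n_presence_cells_mean prevalence_mean tss_max_mean
#> 1      30           16                  46.9        0.000844       0.3023
#> 2    1920           16                  12.9        0.923177       0.0986
#>   tss_max_sd auc_mean
#> 1      0.101    0.599
#> 2      0.137    0.235
```

Reading the table: across the 16 replicated 50 km^2 extents, coarsening
the grain from 30 m to 1920 m collapses a mean of 46.9 presence cells at
prevalence 8.4e-4 into 12.9 cells at prevalence 0.92 — at the coarsest
grain nearly every remaining cell is a presence cell, the model can no
longer separate presence from background, and mean maximum TSS falls from
0.30 to 0.10 (AUC from 0.60 to 0.24). This is the aggregation-driven
accuracy loss in small extents that the pipeline is designed to expose;
at larger extents the same comparison shows no such loss.

Permutation importance of the base variables at 30 m, averaged over
replicates and folds:

```r
imp <- aggregate(importance ~ variable,
                 data = subset(run$importance, grain_m == 30), FUN = mean)
imp[order(-imp$importance), ]
#>      variable importance
#> 3   elevation      37.29
#> 4  pct_forest      20.46
#> 1   dist_road      17.62
#> 2 dist_stream      15.32
#> 5       slope       9.32
```

`transfer_experiment()` evaluates models trained at increasingly larger
extents on one nested small extent's own test data, `compare_parsimony()`
tabulates AICc gains/losses (|change| > 2) from adding phenology and
climate variable sets, and `export_maps()` writes aligned cloglog
suitability grids for visual comparison.

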