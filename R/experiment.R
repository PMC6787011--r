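#' Grain availability of the variable sets
#'
#' The `base` set (elevation, slope, percent forest, distance to road,
#' distance to stream) exists at every grain of the ladder; the phenology
#' components join at 240 m and the climate bands at 960 m, mirroring the
#' native resolutions of the corresponding data products.
#'
#' @param varset One of `"base"`, `"base_pheno"`, `"base_pheno_clim"`.
#' @param grains Numeric vector of candidate grains (m).
#' @return The admissible subset of `grains`.
#' @export
varset_grains <- function(varset, grains) {
  switch(varset,
         base = grains,
         base_pheno = grains[grains >= 240],
         base_pheno_clim = grains[grains >= 960],
         stop("unknown variable set: ", varset))
}

BASE_VARS <- c("elevation", "slope", "pct_forest", "dist_road", "dist_stream")
CLIM_VARS <- c("temp_mean", "temp_seasonality", "temp_range",
               "precip_annual", "precip_seasonality")

#' Default experiment configuration
#'
#' @param grains Grain ladder in meters (successive factor-2 aggregations of
#'   the landscape grain).
#' @param varsets Variable sets to run.
#' @param k Number of cross-validation folds.
#' @param n_background Background sample size per extent and grain.
#' @param max_elev Background elevation ceiling (m).
#' @param agg_stat Block statistic for aggregation, `"mean"` or `"median"`.
#' @param pca_threshold,pca_max Cumulative-variance threshold and component
#'   cap for the phenology PCA.
#' @param master_seed Master seed; all child seeds derive from it.
#' @return Named list of settings.
#' @export
experiment_config <- function(grains = 30 * 2^(0:6),
                              varsets = c("base", "base_pheno",
                                          "base_pheno_clim"),
                              k = 5, n_background = 10000, max_elev = 3600,
                              agg_stat = "mean", pca_threshold = 0.99,
                              pca_max = 5, master_seed = 1) {
  list(grains = grains, varsets = varsets, k = k,
       n_background = n_background, max_elev = max_elev, agg_stat = agg_stat,
       pca_threshold = pca_threshold, pca_max = pca_max,
       master_seed = as.integer(master_seed))
}

#' Read an experiment configuration from YAML
#'
#' Reads a YAML file whose keys are the arguments of [experiment_config()]
#' (unknown keys are an error, so typos fail loudly). The raw file can be
#' echoed verbatim into a run's output directory for provenance via
#' [write_results()]'s `config_path` argument.
#'
#' @param path Path to a YAML file.
#' @return Named list as from [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- do.call(experiment_config, raw)
  attr(cfg, "source_path") <- path
  cfg
}

#' Build the multi-grain predictor ladder
#'
#' Successively aggregates the landscape layers by factors of 2 up the grain
#' ladder. The 11 phenology bands are aggregated to the coarsest grain below
#' 240 m available in the ladder's range, reduced to principal components
#' there (threshold and cap from the config), and the components are then
#' aggregated onward; climate bands are carried from 960 m up.
#'
#' @param landscape Result of [make_landscape()].
#' @param config An [experiment_config()].
#' @return Named list (by grain, as character) of named layer lists.
#' @export
build_grain_ladder <- function(landscape, config = experiment_config()) {
  st <- landscape$stack
  base_cell <- st$grain
  grains <- sort(config$grains)
  if (any(abs(grains / base_cell - round(grains / base_cell)) > 1e-9))
    stop("every grain must be an integer multiple of the landscape cell")
  pheno_names <- grep("^pheno_", names(st$layers), value = TRUE)
  ladder <- list()
  prev <- st$layers[c(BASE_VARS, intersect(CLIM_VARS, names(st$layers)))]
  prev_grain <- base_cell
  pheno_pcs <- NULL
  raw_pheno <- st$layers[pheno_names]
  for (g in grains) {
    f <- as.integer(round(g / prev_grain))
    if (f > 1L) {
      prev <- lapply(prev, aggregate_raster, factor = f,
                     stat = config$agg_stat)
      if (!is.null(pheno_pcs))
        pheno_pcs <- lapply(pheno_pcs, aggregate_raster, factor = f,
                            stat = config$agg_stat)
      if (!is.null(raw_pheno))
        raw_pheno <- lapply(raw_pheno, aggregate_raster, factor = f,
                            stat = config$agg_stat)
      prev_grain <- g
    }
    if (is.null(pheno_pcs) && g >= 240 && length(raw_pheno) > 0) {
      pcs <- pca_reduce(raw_pheno, variance_threshold = config$pca_threshold,
                        max_components = config$pca_max, prefix = "pheno_pc")
      pheno_pcs <- pcs$layers
      raw_pheno <- NULL
    }
    layers <- prev
    if (!is.null(pheno_pcs)) layers <- c(layers, pheno_pcs)
    ladder[[as.character(g)]] <- layers
  }
  ladder
}

.varset_layers <- function(layers, varset) {
  nm <- switch(varset,
               base = BASE_VARS,
               base_pheno = c(BASE_VARS, grep("^pheno_pc", names(layers),
                                              value = TRUE)),
               base_pheno_clim = c(BASE_VARS,
                                   grep("^pheno_pc", names(layers),
                                        value = TRUE),
                                   intersect(CLIM_VARS, names(layers))))
  layers[nm]
}

.empty_result_row <- function() {
  data.frame(extent_level = integer(0), replicate_id = character(0),
             grain_m = numeric(0), variable_set = character(0),
             fold = character(0), status = character(0),
             n_presence_cells = integer(0), n_presence_points = integer(0),
             prevalence = numeric(0), auc = numeric(0), tss_max = numeric(0),
             tss_threshold = numeric(0), cor = numeric(0), aicc = numeric(0),
             n_presence_test = integer(0), n_background = integer(0))
}

#' Run the factorial scale experiment
#'
#' For every extent replicate, admissible grain, and admissible variable set:
#' crop the grain ladder to the extent, rasterize the presences, sample
#' background (all eligible cells when fewer than requested), split presence
#' cells into folds, fit the maximum-entropy model per fold, and evaluate.
#' Design cells with fewer presence cells than folds are recorded as skipped
#' rows rather than errors. All randomness derives deterministically from the
#' master seed per design cell, so reruns are byte-identical and adding
#' design cells never perturbs existing ones.
#'
#' @param landscape Result of [make_landscape()].
#' @param extents List of [extent_spec()] replicates to model.
#' @param presences Data frame of presence points (`x`, `y`).
#' @param config An [experiment_config()].
#' @param ladder Optional precomputed [build_grain_ladder()] result.
#' @param verbose Print progress lines.
#' @return List with `results` (tidy metric rows, per fold plus a `"mean"`
#'   row) and `importance` (long per-variable permutation importances for the
#'   fold-averaged models).
#' @export
run_factorial <- function(landscape, extents, presences,
                          config = experiment_config(), ladder = NULL,
                          verbose = FALSE) {
  if (is.null(ladder)) ladder <- build_grain_ladder(landscape, config)
  results <- list()
  importance <- list()
  for (ext in extents) {
    for (g in config$grains) {
      layers_g <- ladder[[as.character(g)]]
      cropped <- tryCatch(lapply(layers_g, crop_raster, rect = ext$rect),
                          error = function(e) NULL)
      for (vs in config$varsets) {
        if (!g %in% varset_grains(vs, config$grains)) next
        cellseed <- derive_seed(config$master_seed, ext$replicate_id, g)
        row0 <- data.frame(extent_level = ext$level,
                           replicate_id = ext$replicate_id,
                           grain_m = g, variable_set = vs,
                           fold = NA_character_, status = "ok",
                           n_presence_cells = NA_integer_,
                           n_presence_points = NA_integer_,
                           prevalence = NA_real_, auc = NA_real_,
                           tss_max = NA_real_, tss_threshold = NA_real_,
                           cor = NA_real_, aicc = NA_real_,
                           n_presence_test = NA_integer_,
                           n_background = NA_integer_)
        if (is.null(cropped)) {
          row0$status <- "skipped_empty_extent"
          results[[length(results) + 1L]] <- row0
          next
        }
        use <- .varset_layers(cropped, vs)
        tmpl <- use[[1]]
        # membership by template cell, so points in the partial edge strip
        # of a coarse-grain crop are excluded silently, not warned about
        inext <- point_to_cell(tmpl, presences$x, presences$y)$inside
        pg <- rasterize_presence(presences[inext, , drop = FALSE], tmpl)
        row0$n_presence_cells <- pg$n_cells
        row0$n_presence_points <- pg$n_points
        row0$prevalence <- pg$prevalence
        if (pg$n_cells < config$k) {
          row0$status <- "skipped_too_few_presence_cells"
          results[[length(results) + 1L]] <- row0
          next
        }
        ctr <- cell_centers(pg$mask)
        pres_idx <- which(pg$mask$values[cbind(ctr$row, ctr$col)] == 1)
        pres_xy <- ctr[pres_idx, c("x", "y")]
        stk <- predictor_stack(vs, use, grain = g)
        pres_vals <- stack_values(stk, pres_xy$x, pres_xy$y)
        bg_xy <- tryCatch(
          sample_background(ext, tmpl, use[["elevation"]],
                            n = config$n_background,
                            max_elev = config$max_elev,
                            seed = derive_seed(cellseed, "background")),
          error = function(e) NULL)
        if (is.null(bg_xy)) {
          row0$status <- "skipped_no_background"
          results[[length(results) + 1L]] <- row0
          next
        }
        bg_vals <- stack_values(stk, bg_xy$x, bg_xy$y)
        ok_p <- stats::complete.cases(pres_vals)
        pres_vals <- pres_vals[ok_p, , drop = FALSE]
        if (nrow(pres_vals) < config$k) {
          row0$status <- "skipped_too_few_presence_cells"
          results[[length(results) + 1L]] <- row0
          next
        }
        folds <- kfold_split(nrow(pres_vals), config$k,
                             seed = derive_seed(cellseed, "folds"))
        fold_rows <- list()
        fit_err <- FALSE
        for (fs in folds) {
          m <- tryCatch(
            fit_sdm(pres_vals[fs$train_idx, , drop = FALSE], bg_vals,
                    seed = derive_seed(cellseed, vs, "fit", fs$fold_id),
                    meta = list(extent = ext$replicate_id, grain = g,
                                varset = vs, fold = fs$fold_id,
                                rect = ext$rect)),
            error = function(e) NULL)
          if (is.null(m)) { fit_err <- TRUE; break }
          ev <- evaluate_sdm(m, pres_vals[fs$test_idx, , drop = FALSE],
                             bg_vals,
                             aicc_presence = pres_vals[fs$train_idx, ,
                                                       drop = FALSE])
          ev$fold <- as.character(fs$fold_id)
          fold_rows[[fs$fold_id]] <- ev
          imp <- permutation_importance(
            m, pres_vals[fs$train_idx, , drop = FALSE], bg_vals,
            seed = derive_seed(cellseed, vs, "imp", fs$fold_id))
          importance[[length(importance) + 1L]] <- data.frame(
            extent_level = ext$level, replicate_id = ext$replicate_id,
            grain_m = g, variable_set = vs, fold = as.character(fs$fold_id),
            variable = names(imp), importance = as.numeric(imp))
        }
        if (fit_err) {
          row0$status <- "skipped_fit_error"
          results[[length(results) + 1L]] <- row0
          next
        }
        ev_all <- evaluate_folds(do.call(rbind, fold_rows))
        for (i in seq_len(nrow(ev_all))) {
          row <- row0
          row$fold <- ev_all$fold[i]
          row$auc <- ev_all$auc[i]
          row$tss_max <- ev_all$tss_max[i]
          row$tss_threshold <- ev_all$tss_threshold[i]
          row$cor <- ev_all$cor[i]
          row$aicc <- ev_all$aicc[i]
          row$n_presence_test <- ev_all$n_presence_test[i]
          row$n_background <- ev_all$n_background[i]
          results[[length(results) + 1L]] <- row
        }
        if (verbose)
          message(sprintf("  %s @ %gm [%s]: maxTSS %.3f",
                          ext$replicate_id, g, vs,
                          ev_all$tss_max[ev_all$fold == "mean"]))
      }
    }
  }
  list(results = if (length(results)) do.call(rbind, results)
       else .empty_result_row(),
       importance = if (length(importance)) do.call(rbind, importance)
       else data.frame())
}

#' Summarize replicates per extent level, grain and variable set
#'
#' Mean and sample SD over the replicate fold-averaged rows, including the
#' presence-cell and prevalence columns. A summarized cell backed by a single
#' replicate reports SD 0 and is flagged.
#'
#' @param results The `results` element of [run_factorial()].
#' @return Data frame with `*_mean` and `*_sd` columns, `n_replicates` and
#'   `single_replicate`.
#' @export
summarize_replicates <- function(results) {
  ok <- results[results$status == "ok" & results$fold == "mean", , drop = FALSE]
  if (nrow(ok) == 0L) return(data.frame())
  key <- interaction(ok$extent_level, ok$grain_m, ok$variable_set, drop = TRUE)
  metrics <- c("auc", "tss_max", "tss_threshold", "cor", "aicc",
               "n_presence_cells", "prevalence")
  out <- lapply(split(ok, key), function(d) {
    row <- data.frame(extent_level = d$extent_level[1],
                      grain_m = d$grain_m[1],
                      variable_set = d$variable_set[1],
                      n_replicates = nrow(d),
                      single_replicate = nrow(d) == 1L)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- if (nrow(d) > 1L)
        stats::sd(d[[m]], na.rm = TRUE) else 0
    }
    row
  })
  out <- do.call(rbind, out)
  out <- out[order(out$variable_set, out$extent_level, out$grain_m), ]
  rownames(out) <- NULL
  out
}

#' Environmental gradient and heterogeneity table
#'
#' For every extent replicate, computes the mean (gradient placement) and SD
#' (heterogeneity) of each predictor over the replicate's valid cells at the
#' native landscape grain, joined to the replicate's fold-averaged accuracy
#' at the requested variable set and grain.
#'
#' @param results The `results` element of [run_factorial()].
#' @param landscape Result of [make_landscape()].
#' @param extents The extent list passed to [run_factorial()].
#' @param varset,grain Which factorial cell's accuracy to pair with.
#' @param variables Predictors to profile (default the base set).
#' @return Long data frame: one row per replicate x variable.
#' @export
gradient_analysis <- function(results, landscape, extents, varset = "base",
                              grain = NULL, variables = BASE_VARS) {
  miss <- setdiff(variables, names(landscape$stack$layers))
  if (length(miss) > 0L)
    stop("unknown variable(s): ", paste(miss, collapse = ", "))
  if (is.null(grain)) grain <- landscape$stack$grain
  acc <- results[results$status == "ok" & results$fold == "mean" &
                   results$variable_set == varset &
                   results$grain_m == grain, , drop = FALSE]
  out <- list()
  for (ext in extents) {
    a <- acc[acc$replicate_id == ext$replicate_id, , drop = FALSE]
    if (nrow(a) == 0L) next
    for (v in variables) {
      vals <- crop_raster(landscape$stack$layers[[v]], ext$rect)$values
      out[[length(out) + 1L]] <- data.frame(
        replicate_id = ext$replicate_id, extent_level = ext$level,
        variable = v, mean_value = mean(vals, na.rm = TRUE),
        sd_value = stats::sd(as.vector(vals), na.rm = TRUE),
        auc = a$auc[1], tss_max = a$tss_max[1], cor = a$cor[1])
    }
  }
  if (length(out) == 0L) return(data.frame())
  do.call(rbind, out)
}

#' Parsimony comparison between variable sets
#'
#' For each comparison (base vs base+phenology at 240 m, base+phenology vs
#' base+phenology+climate at 960 m, base vs base+phenology+climate at 960 m)
#' and extent level, classifies every replicate by the AICc change when the
#' richer set is added: `minus` (AICc up by more than `delta`: reduced
#' parsimony), `plus` (down by more than `delta`: improved), `nochange`
#' (within `delta`). The three fractions sum to 1 over the comparable
#' replicates; replicates with a not-computable AICc are excluded and
#' counted.
#'
#' @param results The `results` element of [run_factorial()].
#' @param delta AICc difference treated as meaningful (default 2).
#' @return Data frame with one row per comparison x extent level.
#' @export
compare_parsimony <- function(results, delta = 2) {
  comparisons <- list(
    list(a = "base", b = "base_pheno", grain = 240),
    list(a = "base_pheno", b = "base_pheno_clim", grain = 960),
    list(a = "base", b = "base_pheno_clim", grain = 960)
  )
  ok <- results[results$status == "ok" & results$fold == "mean", , drop = FALSE]
  out <- list()
  for (cmp in comparisons) {
    a <- ok[ok$variable_set == cmp$a & ok$grain_m == cmp$grain, , drop = FALSE]
    b <- ok[ok$variable_set == cmp$b & ok$grain_m == cmp$grain, , drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    m <- merge(a[, c("extent_level", "replicate_id", "aicc")],
               b[, c("extent_level", "replicate_id", "aicc")],
               by = c("extent_level", "replicate_id"),
               suffixes = c("_a", "_b"))
    for (lev in sort(unique(m$extent_level))) {
      d <- m[m$extent_level == lev, , drop = FALSE]
      usable <- is.finite(d$aicc_a) & is.finite(d$aicc_b)
      n_exc <- sum(!usable)
      d <- d[usable, , drop = FALSE]
      if (nrow(d) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          comparison = paste(cmp$a, cmp$b, sep = " vs "),
          grain_m = cmp$grain, extent_level = lev, n = 0L,
          n_excluded = n_exc, minus = NA_real_, plus = NA_real_,
          nochange = NA_real_)
        next
      }
      dd <- d$aicc_b - d$aicc_a
      out[[length(out) + 1L]] <- data.frame(
        comparison = paste(cmp$a, cmp$b, sep = " vs "),
        grain_m = cmp$grain, extent_level = lev, n = nrow(d),
        n_excluded = n_exc,
        minus = mean(dd > delta),
        plus = mean(dd < -delta),
        nochange = mean(abs(dd) <= delta))
    }
  }
  if (length(out) == 0L) return(data.frame())
  do.call(rbind, out)
}

#' Cross-extent transfer experiment
#'
#' Fits base-variable models at the native grain for a target level-1 extent
#' and each containing source extent, and evaluates every source model on the
#' target's own test folds and background — identical test data for all
#' sources. For fold `f`, each source trains on its presence cells minus the
#' target's fold-`f` test cells (no leakage) and is scored on those test
#' cells vs the target background.
#'
#' @param landscape Result of [make_landscape()].
#' @param sources Named list of [extent_spec()] (must all contain the
#'   target; may include the target itself).
#' @param target An [extent_spec()] (level 1).
#' @param presences Data frame of presence points.
#' @param config An [experiment_config()] (its `k`, `n_background`,
#'   `max_elev` and `master_seed` are used; grain is the landscape grain).
#' @return List with `metrics` (tidy rows per source x fold plus means) and
#'   `models` (one full-data model per source, for mapping).
#' @export
transfer_experiment <- function(landscape, sources, target, presences,
                                config = experiment_config()) {
  st <- landscape$stack
  g <- st$grain
  for (s in sources)
    if (!rect_contains(s$rect, target$rect))
      stop("source '", s$replicate_id, "' does not contain the target")
  base_stack <- predictor_stack("base", st$layers[BASE_VARS], grain = g)
  tmpl <- base_stack$layers[[1]]

  cell_of <- function(xy) {
    idx <- point_to_cell(tmpl, xy$x, xy$y)
    paste(idx$row, idx$col)
  }
  pres_cells <- function(rect) {
    tm <- crop_raster(tmpl, rect)
    keep <- point_to_cell(tm, presences$x, presences$y)$inside
    pg <- rasterize_presence(presences[keep, , drop = FALSE], tm)
    ctr <- cell_centers(pg$mask)
    sel <- which(pg$mask$values[cbind(ctr$row, ctr$col)] == 1)
    ctr[sel, c("x", "y")]
  }
  tgt_xy <- pres_cells(target$rect)
  if (nrow(tgt_xy) < config$k)
    stop("target has fewer presence cells than folds")
  tgt_vals <- stack_values(base_stack, tgt_xy$x, tgt_xy$y)
  tgt_keys <- cell_of(tgt_xy)
  seed0 <- derive_seed(config$master_seed, "transfer", target$replicate_id)
  folds <- kfold_split(nrow(tgt_xy), config$k, seed = derive_seed(seed0, "folds"))
  tgt_bg <- sample_background(target, tmpl, st$layers[["elevation"]],
                              n = config$n_background,
                              max_elev = config$max_elev,
                              seed = derive_seed(seed0, "bg"))
  tgt_bg_vals <- stack_values(base_stack, tgt_bg$x, tgt_bg$y)

  metrics <- list()
  models <- list()
  for (nm in names(sources)) {
    src <- sources[[nm]]
    src_xy <- pres_cells(src$rect)
    src_keys <- cell_of(src_xy)
    src_vals <- stack_values(base_stack, src_xy$x, src_xy$y)
    src_bg <- sample_background(src, tmpl, st$layers[["elevation"]],
                                n = config$n_background,
                                max_elev = config$max_elev,
                                seed = derive_seed(seed0, "bg_src", nm))
    src_bg_vals <- stack_values(base_stack, src_bg$x, src_bg$y)
    rows <- list()
    for (fs in folds) {
      test_keys <- tgt_keys[fs$test_idx]
      train <- src_vals[!(src_keys %in% test_keys), , drop = FALSE]
      train <- train[stats::complete.cases(train), , drop = FALSE]
      m <- fit_sdm(train, src_bg_vals,
                   seed = derive_seed(seed0, "fit", nm, fs$fold_id),
                   meta = list(extent = src$replicate_id, grain = g,
                               varset = "base", fold = fs$fold_id,
                               rect = src$rect))
      ev <- transfer_evaluate(m, target,
                              tgt_vals[fs$test_idx, , drop = FALSE],
                              tgt_bg_vals)
      ev$fold <- as.character(fs$fold_id)
      rows[[fs$fold_id]] <- ev
    }
    ev_all <- evaluate_folds(do.call(rbind, rows))
    ev_all$source <- nm
    ev_all$source_level <- src$level
    ev_all$target <- target$replicate_id
    metrics[[nm]] <- ev_all
    train_all <- src_vals[stats::complete.cases(src_vals), , drop = FALSE]
    models[[nm]] <- fit_sdm(train_all, src_bg_vals,
                            seed = derive_seed(seed0, "fit_full", nm),
                            meta = list(extent = src$replicate_id, grain = g,
                                        varset = "base", fold = "full",
                                        rect = src$rect))
  }
  list(metrics = do.call(rbind, metrics), models = models,
       target_background = tgt_bg_vals, target_presence = tgt_vals)
}

#' Export suitability maps of source models over a target extent
#'
#' Writes one cloglog suitability grid (ESRI ASCII) per source model over the
#' common target extent, plus a sidecar CSV of each model's transfer metrics.
#' All grids share shape, origin and cell size exactly.
#'
#' @param models Named list of fitted models (with `meta$rect` set).
#' @param landscape Result of [make_landscape()].
#' @param target An [extent_spec()] nested in every model's training extent.
#' @param test_presence,background Data frames of target predictor values for
#'   the sidecar metrics.
#' @param outdir Output directory (created if needed).
#' @return Invisible character vector of the grid paths.
#' @export
export_maps <- function(models, landscape, target, test_presence, background,
                        outdir) {
  if (length(models) < 2L)
    stop("need fitted models for at least 2 source extents")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st <- landscape$stack
  vars <- unique(unlist(lapply(models, function(m) m$transform$vars)))
  tgt_stack <- crop_stack(
    predictor_stack("map", st$layers[vars], grain = st$grain), target$rect)
  paths <- character(0)
  sidecar <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    if (!is.null(m$meta$rect) && !rect_contains(m$meta$rect, target$rect))
      stop("model '", nm, "' was not trained on an extent containing the target")
    pred <- predict(m, tgt_stack, scale = "cloglog")
    p <- file.path(outdir, paste0("suitability_", nm, ".asc"))
    write_esri_ascii(pred, p)
    paths <- c(paths, p)
    ev <- transfer_evaluate(m, target, test_presence, background)
    ev$source <- nm
    sidecar[[nm]] <- ev
  }
  utils::write.csv(do.call(rbind, sidecar),
                   file.path(outdir, "map_metrics.csv"), row.names = FALSE)
  invisible(paths)
}

#' Write factorial results to a directory
#'
#' Writes `results.csv`, `importance.csv`, `summary.csv` and, when level-2+
#' AICc comparisons exist, `parsimony.csv`, with a fixed column order and
#' 15-significant-digit formatting so identical runs are byte-identical.
#'
#' @param run Result of [run_factorial()].
#' @param outdir Output directory.
#' @param config_path Optional path to the YAML config that produced the run;
#'   copied verbatim into `outdir` as `config.yaml` for provenance.
#' @return Invisible `outdir`.
#' @export
write_results <- function(run, outdir, config_path = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config_path) && file.exists(config_path))
    file.copy(config_path, file.path(outdir, "config.yaml"), overwrite = TRUE)
  fmt <- function(df) {
    for (cn in names(df))
      if (is.numeric(df[[cn]])) df[[cn]] <- formatC(df[[cn]], format = "g",
                                                    digits = 15)
    df
  }
  utils::write.csv(fmt(run$results), file.path(outdir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt(run$importance), file.path(outdir, "importance.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt(summarize_replicates(run$results)),
                   file.path(outdir, "summary.csv"), row.names = FALSE)
  pars <- compare_parsimony(run$results)
  if (nrow(pars) > 0L)
    utils::write.csv(fmt(pars), file.path(outdir, "parsimony.csv"),
                     row.names = FALSE)
  invisible(outdir)
}
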