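# a small factorial run shared by the tests below
experiment_fixture <- function() {
  cached("experiment_fixture", function() {
    w <- small_world()
    blocks <- grid_blocks(w$domain, w$pts, block_area_km2 = 4,
                          min_presence = 15)
    cfg <- experiment_config(grains = c(30, 240, 960), k = 3,
                             n_background = 1500, master_seed = 11)
    run <- run_factorial(w$land, blocks[1:3], w$pts, cfg)
    list(w = w, blocks = blocks[1:3], cfg = cfg, run = run)
  })
}

test_that("the factorial attempts exactly the admissible design cells", {
  fx <- experiment_fixture()
  res <- fx$run$results

  # grain availability: base at all grains, phenology >= 240, climate >= 960
  expect_equal(varset_grains("base", 30 * 2^(0:6)), 30 * 2^(0:6))
  expect_equal(varset_grains("base_pheno", 30 * 2^(0:6)),
               c(240, 480, 960, 1920))
  expect_equal(varset_grains("base_pheno_clim", 30 * 2^(0:6)), c(960, 1920))

  per_rep <- table(res$replicate_id[res$fold %in% c("mean", NA) |
                                      startsWith(res$status, "skipped")])
  # per replicate: base x 3 grains + base_pheno x 2 + base_pheno_clim x 1
  # design cells, each contributing either fold rows + mean or one skip row
  for (b in fx$blocks) {
    d <- res[res$replicate_id == b$replicate_id, ]
    cells <- unique(d[, c("grain_m", "variable_set")])
    expect_equal(nrow(cells), 3 + 2 + 1)
  }

  # accounting: every design cell is either ok (k folds + mean) or skipped
  for (b in fx$blocks) for (g in fx$cfg$grains) {
    for (vs in fx$cfg$varsets) {
      if (!g %in% varset_grains(vs, fx$cfg$grains)) next
      d <- res[res$replicate_id == b$replicate_id & res$grain_m == g &
                 res$variable_set == vs, ]
      if (d$status[1] == "ok") expect_equal(nrow(d), fx$cfg$k + 1L)
      else expect_equal(nrow(d), 1L)
    }
  }
})

test_that("factorial reruns with the same master seed are identical", {
  fx <- experiment_fixture()
  rerun <- run_factorial(fx$w$land, fx$blocks, fx$w$pts, fx$cfg)
  expect_identical(fx$run$results, rerun$results)
  expect_identical(fx$run$importance, rerun$importance)
})

test_that("prevalence recorded in results matches the presence grid", {
  fx <- experiment_fixture()
  res <- fx$run$results
  b <- fx$blocks[[1]]
  d <- res[res$replicate_id == b$replicate_id & res$grain_m == 30 &
             res$variable_set == "base" & res$fold == "mean", ]
  tmpl <- crop_raster(fx$w$land$stack$layers$elevation, b$rect)
  keep <- fx$w$pts$x >= b$rect[1] & fx$w$pts$x < b$rect[3] &
    fx$w$pts$y >= b$rect[2] & fx$w$pts$y < b$rect[4]
  pg <- rasterize_presence(fx$w$pts[keep, ], tmpl)
  expect_equal(d$n_presence_cells, pg$n_cells)
  expect_equal(d$prevalence, pg$prevalence)
})

test_that("replicate summaries are hand-checkable means and SDs", {
  fake <- data.frame(
    extent_level = 1, replicate_id = c("a", "b", "c"), grain_m = 30,
    variable_set = "base", fold = "mean", status = "ok",
    n_presence_cells = c(10L, 20L, 30L), n_presence_points = c(12L, 25L, 33L),
    prevalence = c(0.1, 0.2, 0.3), auc = c(0.6, 0.7, 0.8),
    tss_max = c(0.4, 0.6, 0.5), tss_threshold = 0.5, cor = c(0.2, 0.3, 0.4),
    aicc = c(100, 110, 120), n_presence_test = 3L, n_background = 100L)
  s <- summarize_replicates(fake)
  expect_equal(nrow(s), 1L)
  expect_equal(s$n_replicates, 3L)
  expect_equal(s$tss_max_mean, 0.5)
  expect_equal(s$tss_max_sd, sd(c(0.4, 0.6, 0.5)))
  expect_equal(s$n_presence_cells_mean, 20)
  expect_equal(s$prevalence_mean, 0.2)

  # two-replicate arithmetic: tss 0.4/0.6 -> mean 0.5, sd ~ 0.1414
  s2 <- summarize_replicates(fake[1:2, ])
  expect_equal(s2$tss_max_mean, 0.5)
  expect_equal(s2$tss_max_sd, sd(c(0.4, 0.6)), tolerance = 1e-9)

  # single replicate: SD zero and flagged
  s1 <- summarize_replicates(fake[1, ])
  expect_true(s1$single_replicate)
  expect_equal(s1$tss_max_sd, 0)
})

test_that("gradient analysis pairs predictor summaries with accuracy", {
  fx <- experiment_fixture()
  gr <- gradient_analysis(fx$run$results, fx$w$land, fx$blocks,
                          varset = "base", grain = 30)
  n_ok <- length(unique(gr$replicate_id))
  expect_equal(nrow(gr), n_ok * 5L)  # base variables

  b <- fx$blocks[[1]]
  vals <- crop_raster(fx$w$land$stack$layers$pct_forest, b$rect)$values
  row <- gr[gr$replicate_id == b$replicate_id & gr$variable == "pct_forest", ]
  expect_equal(row$mean_value, mean(vals, na.rm = TRUE))
  expect_equal(row$sd_value, sd(as.vector(vals), na.rm = TRUE))

  expect_error(gradient_analysis(fx$run$results, fx$w$land, fx$blocks,
                                 variables = "nope"), "unknown")
})

test_that("parsimony fractions partition the replicates", {
  fx <- experiment_fixture()
  pars <- compare_parsimony(fx$run$results, delta = 2)
  if (nrow(pars) > 0) {
    ok <- !is.na(pars$minus)
    expect_true(all(abs(pars$minus[ok] + pars$plus[ok] +
                          pars$nochange[ok] - 1) < 1e-12))
    expect_equal(sort(unique(pars$grain_m)), c(240, 960))
  }

  # identical models: everything lands in the no-change class
  base_rows <- data.frame(
    extent_level = 1, replicate_id = c("a", "b"), grain_m = 240,
    variable_set = "base", fold = "mean", status = "ok",
    n_presence_cells = 5L, n_presence_points = 5L, prevalence = 0.1,
    auc = 0.7, tss_max = 0.5, tss_threshold = 0.5, cor = 0.3,
    aicc = c(100, 200), n_presence_test = 2L, n_background = 10L)
  pheno_rows <- base_rows
  pheno_rows$variable_set <- "base_pheno"
  p <- compare_parsimony(rbind(base_rows, pheno_rows))
  expect_equal(p$minus, 0)
  expect_equal(p$plus, 0)
  expect_equal(p$nochange, 1)

  # NA AICc replicates are excluded and counted
  pheno_rows$aicc[1] <- NA
  p2 <- compare_parsimony(rbind(base_rows, pheno_rows))
  expect_equal(p2$n_excluded, 1L)
  expect_equal(p2$n, 1L)
})

test_that("YAML configs round-trip into experiment settings", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("grains: [30, 240]", "varsets: [base]", "k: 3",
               "n_background: 1234", "master_seed: 99"), p)
  cfg <- read_experiment_config(p)
  expect_equal(cfg$grains, c(30, 240))
  expect_equal(cfg$varsets, "base")
  expect_equal(cfg$k, 3)
  expect_equal(cfg$n_background, 1234)
  expect_equal(cfg$master_seed, 99L)
  expect_equal(cfg$max_elev, 3600)  # defaults fill the rest

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_bakground: 10", bad)
  expect_error(read_experiment_config(bad), "unknown config key")

  # config echoed verbatim next to the results
  run <- experiment_fixture()$run
  d <- withr::local_tempdir()
  write_results(run, d, config_path = p)
  expect_identical(readLines(file.path(d, "config.yaml")), readLines(p))
})

test_that("results directory export is byte-stable across identical runs", {
  fx <- experiment_fixture()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_results(fx$run, d1)
  rerun <- run_factorial(fx$w$land, fx$blocks, fx$w$pts, fx$cfg)
  write_results(rerun, d2)
  for (f in c("results.csv", "importance.csv", "summary.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))))
  }
})

test_that("transfer experiment scores all sources on identical test data", {
  fx <- experiment_fixture()
  w <- fx$w
  target <- fx$blocks[[1]]
  big <- extent_spec(4, "L4", w$domain[c("xmin", "ymin", "xmax", "ymax")])
  cfg <- experiment_config(k = 3, n_background = 1000, master_seed = 5)
  tr <- transfer_experiment(w$land, list(target = target, global = big),
                            target, w$pts, cfg)
  m <- tr$metrics
  expect_setequal(unique(m$source), c("target", "global"))
  # per source: k fold rows plus the mean row
  expect_equal(sum(m$source == "target"), cfg$k + 1L)
  expect_true(all(m$target == target$replicate_id))
  # identical test sizes per fold across sources
  for (f in as.character(1:cfg$k)) {
    sizes <- m$n_presence_test[m$fold == f]
    expect_equal(length(unique(sizes)), 1L)
  }
  expect_error(
    transfer_experiment(w$land,
                        list(bad = extent_spec(1, "bad", c(0, 0, 900, 900))),
                        target, w$pts, cfg),
    "does not contain")

  # map export: aligned grids plus sidecar metrics equal transfer output
  outdir <- withr::local_tempdir()
  paths <- export_maps(tr$models, w$land, target, tr$target_presence,
                       tr$target_background, outdir)
  expect_length(paths, 2L)
  g1 <- read_esri_ascii(paths[1]); g2 <- read_esri_ascii(paths[2])
  expect_equal(dim(g1$values), dim(g2$values))
  expect_equal(g1$x0, g2$x0)
  expect_equal(g1$cell, g2$cell)
  side <- utils::read.csv(file.path(outdir, "map_metrics.csv"))
  ev <- transfer_evaluate(tr$models$target, target, tr$target_presence,
                          tr$target_background)
  expect_equal(side$auc[side$source == "target"], ev$auc, tolerance = 1e-9)
})
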