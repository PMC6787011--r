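test_that("block aggregation computes block statistics and handles nodata", {
  r <- raster_grid(matrix(1:16, 4, 4, byrow = TRUE), x0 = 0, y0 = 120,
                   cell = 30)
  a <- aggregate_raster(r, 2, "mean")
  expect_equal(a$values, matrix(c(3.5, 11.5, 5.5, 13.5), 2, 2))
  expect_equal(a$cell, 60)

  expect_identical(aggregate_raster(r, 1), r)

  med <- aggregate_raster(r, 2, "median")
  expect_equal(med$values[1, 1], median(c(1, 2, 5, 6)))

  # mixed blocks use valid cells only; all-nodata blocks become nodata
  v <- matrix(1:16, 4, 4, byrow = TRUE)
  v[1, 1] <- NA; v[3:4, 1:2] <- NA
  an <- aggregate_raster(raster_grid(v, 0, 120, 30), 2, "mean")
  expect_equal(an$values[1, 1], mean(c(2, 5, 6)))
  expect_true(is.na(an$values[2, 1]))

  # trailing rows/cols that do not fill a block are dropped
  r5 <- raster_grid(matrix(1, 5, 5), 0, 150, 30)
  expect_equal(dim(aggregate_raster(r5, 2)$values), c(2L, 2L))

  expect_error(aggregate_raster(r, 0), "positive")
  expect_error(aggregate_raster(r, 5), "smaller")
})

test_that("successive factor-2 aggregation walks the full grain ladder", {
  r <- raster_grid(matrix(rnorm(128 * 128), 128, 128), 0, 128 * 30, 30)
  cells <- numeric(0)
  cur <- r
  for (i in 1:6) {
    cur <- aggregate_raster(cur, 2, "mean")
    cells <- c(cells, cur$cell)
  }
  expect_equal(cells, c(60, 120, 240, 480, 960, 1920))
})

test_that("mean aggregation preserves the global mean and composes", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      v <- matrix(rnorm(24 * 16), 24, 16)
      r <- raster_grid(v, 0, 24 * 30, 30)
      a <- aggregate_raster(r, 4, "mean")
      expect_equal(mean(a$values), mean(v), tolerance = 1e-12)
      two <- aggregate_raster(aggregate_raster(r, 2), 2)
      expect_equal(two$values, a$values, tolerance = 1e-12)
    }
  })
})

test_that("bilinear resampling is exact on constants and affine surfaces", {
  k <- raster_grid(matrix(3.25, 10, 10), 0, 300, 30)
  for (tc in c(10, 45, 100)) {
    out <- bilinear_resample(k, tc)
    expect_true(all(abs(out$values - 3.25) < 1e-12))
    expect_equal(out$cell, tc)
  }

  # f(x, y) = 2x - 0.5y + 7 sampled at cell centers is reproduced exactly
  n <- 20
  ctr_x <- (seq_len(n) - 0.5) * 30
  ctr_y <- n * 30 - (seq_len(n) - 0.5) * 30
  f <- function(x, y) 2 * x - 0.5 * y + 7
  v <- outer(seq_len(n), seq_len(n),
             function(i, j) f(ctr_x[j], ctr_y[i]))
  r <- raster_grid(v, 0, n * 30, 30)
  out <- bilinear_resample(r, 45)
  m <- dim(out$values)
  ox <- (seq_len(m[2]) - 0.5) * 45
  oy <- n * 30 - (seq_len(m[1]) - 0.5) * 45
  # interior centers (inside the input center lattice; edges clamp)
  for (i in 2:(m[1] - 1)) for (j in 2:(m[2] - 1))
    expect_equal(out$values[i, j], f(ox[j], oy[i]), tolerance = 1e-9)
})

test_that("250 m input resampled to 240 m preserves the footprint", {
  r <- raster_grid(matrix(rnorm(100), 10, 10), 0, 2500, 250)
  out <- bilinear_resample(r, 240)
  expect_equal(out$cell, 240)
  ein <- raster_extent(r); eout <- raster_extent(out)
  expect_lt(abs(eout["xmax"] - ein["xmax"]), 240)
  expect_lt(abs(eout["ymin"] - ein["ymin"]), 240)
  expect_error(bilinear_resample(raster_grid(matrix(NA_real_, 3, 3), 0, 90, 30),
                                 60), "all-nodata")
})

test_that("Horn slope matches the stencil oracle and analytic cases", {
  flat <- raster_grid(matrix(500, 6, 6), 0, 180, 30)
  expect_true(all(slope_from_dem(flat)$values == 0))

  # plane rising 1 m per m eastward: 45 degrees in the interior
  n <- 8
  plane <- outer(seq_len(n), seq_len(n), function(i, j) (j - 0.5) * 30)
  s <- slope_from_dem(raster_grid(plane, 0, n * 30, 30))
  expect_true(all(abs(s$values[2:(n - 1), 2:(n - 1)] - 45) < 1e-9))

  withr::with_seed(5, {
    for (rep in 1:10) {
      m <- matrix(rnorm(9, 1000, 50), 3, 3)
      s3 <- slope_from_dem(raster_grid(m, 0, 90, 30))
      expect_equal(s3$values[2, 2], oracle_horn_center(m, 30),
                   tolerance = 1e-12)
    }
  })
  expect_error(slope_from_dem(raster_grid(matrix(1, 2, 5), 0, 60, 30)), "3x3")
})

test_that("distance rasters are exact center-to-feature distances", {
  g <- raster_grid(matrix(0, 10, 10), 0, 300, 30)
  # feature point on a cell center -> that cell has distance 0
  pt <- matrix(c(45, 255), 1, 2)
  d <- distance_raster(list(pt), g)
  expect_equal(d$values[2, 2], 0)

  # brute-force nearest-feature check over all cells, point + polyline
  line <- cbind(c(10, 290), c(20, 290))
  d2 <- distance_raster(list(pt, line), g)
  ctr <- cell_centers(g)
  # dense sampling along the segment as the brute-force reference
  ts <- seq(0, 1, length.out = 200001)
  sx <- 10 + ts * 280; sy <- 20 + ts * 270
  for (k in sample(nrow(ctr), 25)) {
    dp <- sqrt((ctr$x[k] - 45)^2 + (ctr$y[k] - 255)^2)
    best <- min(dp, min(sqrt((ctr$x[k] - sx)^2 + (ctr$y[k] - sy)^2)))
    expect_equal(d2$values[ctr$row[k], ctr$col[k]], best, tolerance = 1e-5)
  }

  # monotone along a ray away from an isolated point
  row2 <- d$values[2, 2:10]
  expect_true(all(diff(row2) > 0))

  expect_error(distance_raster(list(), g), "non-empty")
})

test_that("presence rasterization follows the binning and prevalence rules", {
  g <- raster_grid(matrix(0, 10, 10), 0, 300, 30)
  # two points 10 m apart in one 30 m cell
  pg <- rasterize_presence(data.frame(x = c(40, 50), y = c(100, 100)), g)
  expect_equal(pg$n_cells, 1L)
  expect_equal(max(pg$counts$values, na.rm = TRUE), 2)

  # two points 40 m apart straddling a 30 m edge: 2 cells at 30 m, 1 at 60 m
  pts <- data.frame(x = c(70, 110), y = c(100, 100))
  pg30 <- rasterize_presence(pts, g)
  expect_equal(pg30$n_cells, 2L)
  g60 <- aggregate_raster(g, 2)
  pg60 <- rasterize_presence(pts, g60)
  expect_equal(pg60$n_cells, 1L)

  # prevalence against valid template cells
  pg3 <- rasterize_presence(data.frame(x = c(15, 105, 285),
                                       y = c(285, 105, 15)), g)
  expect_equal(pg3$prevalence, 0.03)

  # outside points dropped with a warning; empty input is not an error
  expect_warning(rasterize_presence(data.frame(x = -5, y = 100), g),
                 "outside")
  pg0 <- rasterize_presence(data.frame(x = numeric(0), y = numeric(0)), g)
  expect_equal(pg0$n_cells, 0L)
})

test_that("presence cells are non-increasing along the grain ladder", {
  withr::with_seed(21, {
    g <- raster_grid(matrix(0, 128, 128), 0, 128 * 30, 30)
    pts <- data.frame(x = runif(300, 0, 128 * 30), y = runif(300, 0, 128 * 30))
    prev_cells <- Inf
    cur <- g
    for (f in c(1, 2, 2, 2, 2, 2, 2)) {
      if (f > 1) cur <- aggregate_raster(cur, f)
      n <- rasterize_presence(pts, cur)$n_cells
      expect_lte(n, prev_cells)
      prev_cells <- n
    }
  })
})

test_that("PCA reduction retains the right components, orthogonal scores", {
  n <- 40
  withr::with_seed(31, {
    lat1 <- matrix(rnorm(n * n), n, n)
    lat2 <- matrix(rnorm(n * n), n, n)
    mk <- function(a, b, eps = 0.05)
      raster_grid(a * lat1 + b * lat2 + eps * matrix(rnorm(n * n), n, n),
                  0, n * 30, 30)
    bands <- lapply(1:11, function(i) mk(rnorm(1), rnorm(1)))
    names(bands) <- sprintf("b%02d", 1:11)
    red <- pca_reduce(bands, variance_threshold = 0.99)
    expect_lte(length(red$layers), 3L)

    # retained scores are orthogonal in sample covariance
    sc <- sapply(red$layers, function(r) as.vector(r$values))
    cv <- cov(sc[complete.cases(sc), , drop = FALSE])
    off <- cv - diag(diag(cv))
    expect_lt(max(abs(off)), 1e-8)
  })

  # rank-1 case: two identical bands give one component at 100%
  b <- raster_grid(matrix(rnorm(100), 10, 10), 0, 300, 30)
  red1 <- pca_reduce(list(x = b, y = b), variance_threshold = 0.99)
  expect_equal(length(red1$layers), 1L)
  expect_equal(attr(red1, "explained")[1], 1, tolerance = 1e-12)

  # 11-band configuration with threshold 0.99 capped at 5 components
  withr::with_seed(32, {
    bands11 <- lapply(1:11, function(i)
      raster_grid(matrix(rnorm(400), 20, 20), 0, 600, 30))
    names(bands11) <- sprintf("m%02d", 1:11)
    red5 <- pca_reduce(bands11, variance_threshold = 0.99, max_components = 5)
    expect_lte(length(red5$layers), 5L)
  })

  cst <- raster_grid(matrix(1, 10, 10), 0, 300, 30)
  expect_warning(pca_reduce(list(a = b, b = b, c = cst)), "constant")
  expect_error(suppressWarnings(pca_reduce(list(a = cst, b = cst))),
               "constant")
})

test_that("ESRI ASCII round trip is lossless including nodata", {
  v <- matrix(rnorm(30), 5, 6)
  v[2, 3] <- NA
  r <- raster_grid(v, x0 = 1500, y0 = 4500, cell = 30, nodata = -9999)
  p <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(r, p)
  hdr <- readLines(p, n = 6)
  expect_match(hdr[1], "^ncols 6$")
  expect_match(hdr[2], "^nrows 5$")
  expect_match(hdr[3], "^xllcorner 1500$")
  expect_match(hdr[4], "^yllcorner 4350$")
  expect_match(hdr[5], "^cellsize 30$")
  expect_match(hdr[6], "^NODATA_value -9999$")
  back <- read_esri_ascii(p)
  expect_equal(back$values, r$values, tolerance = 1e-12)
  expect_equal(back$x0, r$x0)
  expect_equal(back$y0, r$y0)
  expect_equal(back$cell, r$cell)
})

test_that("point-to-cell mapping uses half-open top-left-anchored cells", {
  r <- raster_grid(matrix(1:12, 3, 4), x0 = 0, y0 = 90, cell = 30)
  # x edges are closed below; the y index is floor((y0 - y)/cell), so a
  # point exactly on an interior horizontal edge belongs to the row below
  idx <- point_to_cell(r, c(0, 29.999, 30, 119), c(89.999, 60, 60, 0.001))
  expect_equal(idx$col, c(1L, 1L, 2L, 4L))
  expect_equal(idx$row, c(1L, 2L, 2L, 3L))
  expect_true(all(idx$inside))
  expect_false(point_to_cell(r, 120, 50)$inside)  # x on the outer edge
})
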