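#' Gaussian random field with controllable autocorrelation range
#'
#' Simulates a zero-mean stationary Gaussian field on a regular grid by
#' convolving white noise with a kernel whose power spectrum matches an
#' exponential covariance `sill * exp(-d / (range_m / 3))` on the torus
#' (circulant spectral synthesis). `range_m` is the practical range: the lag
#' at which correlation has decayed to about 0.05. `range_m = 0` gives i.i.d.
#' noise. Output is bit-identical for a fixed seed.
#'
#' @param nrow,ncol Grid dimensions.
#' @param cell Cell size in meters.
#' @param range_m Practical autocorrelation range in meters, `>= 0`.
#' @param sill Marginal variance, `> 0`.
#' @param seed Integer seed.
#' @param x0,y0 Grid anchor (default top-left at `(0, nrow*cell)`).
#' @return A [raster_grid()].
#' @export
gaussian_field <- function(nrow, ncol, cell = 30, range_m = 0, sill = 1,
                           seed = 1, x0 = 0, y0 = nrow * cell) {
  if (range_m < 0) stop("'range_m' must be >= 0")
  if (sill <= 0) stop("'sill' must be > 0")
  w <- withr::with_seed(seed, matrix(stats::rnorm(nrow * ncol), nrow, ncol))
  if (range_m == 0) {
    return(raster_grid(sqrt(sill) * w, x0 = x0, y0 = y0, cell = cell))
  }
  phi <- range_m / 3 / cell            # e-folding scale in cell units
  # torus lag distances
  di <- pmin(0:(nrow - 1), nrow - (0:(nrow - 1)))
  dj <- pmin(0:(ncol - 1), ncol - (0:(ncol - 1)))
  dist <- sqrt(outer(di^2, dj^2, `+`))
  K <- exp(-dist / phi)
  S <- Re(stats::fft(K))
  S[S < 0] <- 0
  Y <- Re(stats::fft(stats::fft(w) * sqrt(S), inverse = TRUE)) / (nrow * ncol)
  # torus covariance of Y is K up to the spectral truncation; rescale to sill
  v <- mean(S) # theoretical variance of Y equals mean of retained spectrum
  Y <- Y * sqrt(sill / v)
  raster_grid(Y, x0 = x0, y0 = y0, cell = cell)
}

#' Configuration of a synthetic habitat truth
#'
#' Describes a landscape with known suitability: grid shape and cell size, the
#' spatial autocorrelation range of the generated predictor fields, and
#' per-region response coefficients. With `n_regions = 1` the truth is
#' stationary; with 2 (vertical halves) or 4 (quadrants) the response can
#' differ between contiguous regions, emulating range-partitioned populations
#' with locally adapted environmental responses.
#'
#' @param shape Integer `c(nrow, ncol)` of the 30 m landscape grid.
#' @param cell Cell size in meters (default 30).
#' @param field_range Autocorrelation range (m) of the generated fields.
#' @param n_regions 1, 2 or 4 contiguous truth regions.
#' @param coefficients Named list: for each region id (`"1"`, ...) a named list
#'   mapping variable name to `c(linear, quadratic)` coefficients on the
#'   standardized variable. A single unnamed list is recycled to all regions.
#' @param intercepts Numeric vector of per-region intercepts (recycled).
#' @param seed Integer seed driving all generator randomness.
#' @return An object of class `"truth_config"`.
#' @export
truth_config <- function(shape = c(1000, 1000), cell = 30,
                         field_range = 3000, n_regions = 1,
                         coefficients = NULL, intercepts = 0, seed = 1) {
  if (!n_regions %in% c(1, 2, 4)) stop("'n_regions' must be 1, 2 or 4")
  if (is.null(coefficients)) {
    coefficients <- list(
      elevation   = c(0, -1.0),
      pct_forest  = c(1.5, 0),
      slope       = c(-0.5, 0),
      dist_road   = c(0.8, 0),
      dist_stream = c(-0.3, 0)
    )
  }
  # a flat coefficient list is recycled to every region
  if (!is.null(names(coefficients)) &&
      !all(names(coefficients) %in% as.character(seq_len(n_regions)))) {
    coefficients <- stats::setNames(rep(list(coefficients), n_regions),
                                    as.character(seq_len(n_regions)))
  }
  intercepts <- rep_len(intercepts, n_regions)
  structure(list(shape = as.integer(shape), cell = cell,
                 field_range = field_range, n_regions = as.integer(n_regions),
                 coefficients = coefficients, intercepts = intercepts,
                 seed = as.integer(seed)),
            class = "truth_config")
}

# random monotone-ish polyline crossing the full domain, n_seg segments
.random_polyline <- function(ext, n_seg = 6, horizontal = TRUE) {
  w <- ext["xmax"] - ext["xmin"]; h <- ext["ymax"] - ext["ymin"]
  t <- seq(0, 1, length.out = n_seg + 1)
  if (horizontal) {
    x <- ext["xmin"] + t * w
    y <- ext["ymin"] + h * stats::runif(1, 0.15, 0.85) +
      cumsum(c(0, stats::rnorm(n_seg, 0, h * 0.06)))
    y <- pmin(pmax(y, ext["ymin"]), ext["ymax"])
  } else {
    y <- ext["ymin"] + t * h
    x <- ext["xmin"] + w * stats::runif(1, 0.15, 0.85) +
      cumsum(c(0, stats::rnorm(n_seg, 0, w * 0.06)))
    x <- pmin(pmax(x, ext["xmin"]), ext["xmax"])
  }
  cbind(x = as.numeric(x), y = as.numeric(y))
}

#' Generate a synthetic landscape with known truth
#'
#' Builds a 30 m predictor stack emulating the structure of a mountainous
#' forest landscape: autocorrelated elevation with a regional trend, slope
#' derived from the elevation surface, percent forest in `[0, 100]` from a
#' logistic transform of a second field, Euclidean distance rasters to random
#' road and stream polylines, an 11-band phenology stack built as linear
#' mixtures of three latent fields plus noise (so many band pairs correlate
#' above 0.9), and five coarse climate bands generated at 960 m and
#' bilinearly resampled to the landscape grain. A region mask partitions the
#' domain into 1, 2 (vertical halves) or 4 (quadrant) contiguous blocks.
#'
#' @param config A [truth_config()].
#' @return A list with elements `stack` (a [predictor_stack()] at the
#'   landscape grain), `regions` (integer region-id raster), `features`
#'   (road/stream polylines), and `config`.
#' @export
make_landscape <- function(config) {
  nr <- config$shape[1]; nc <- config$shape[2]
  if (nr < 8L || nc < 8L) stop("landscape too small to host features")
  cell <- config$cell
  rng <- config$field_range
  sd0 <- config$seed
  fld <- function(tag, range_m = rng, sill = 1)
    gaussian_field(nr, nc, cell, range_m, sill, seed = derive_seed(sd0, tag))

  # elevation: broad field + south-to-north regional trend, meters
  f_elev <- fld("elev")
  trend <- matrix(rep(seq(0, 1, length.out = nr), nc), nr, nc)
  elev_v <- 2400 + 650 * f_elev$values + 900 * trend
  elevation <- raster_grid(elev_v, 0, nr * cell, cell)
  slope <- slope_from_dem(elevation)

  # percent forest in [0, 100]
  f_for <- fld("forest")
  pct_forest <- raster_grid(pmin(pmax(100 * .invlogit(1.3 * f_for$values), 0), 100),
                            0, nr * cell, cell)

  ext <- raster_extent(elevation)
  feats <- withr::with_seed(derive_seed(sd0, "features"), list(
    roads = list(.random_polyline(ext, horizontal = TRUE),
                 .random_polyline(ext, horizontal = FALSE)),
    streams = list(.random_polyline(ext, horizontal = TRUE),
                   .random_polyline(ext, horizontal = TRUE),
                   .random_polyline(ext, horizontal = FALSE))
  ))
  dist_road <- distance_raster(feats$roads, elevation)
  dist_stream <- distance_raster(feats$streams, elevation)

  layers <- list(elevation = elevation, slope = slope, pct_forest = pct_forest,
                 dist_road = dist_road, dist_stream = dist_stream)

  # 11 phenology bands from 3 latent fields; near-duplicate mixtures give
  # pairwise correlations above 0.9
  lat <- lapply(1:3, function(i) fld(paste0("pheno_latent", i))$values)
  mix <- withr::with_seed(derive_seed(sd0, "pheno_mix"),
                          matrix(stats::rnorm(11 * 3), 11, 3))
  mix[2, ] <- mix[1, ]    # force highly correlated band pairs
  mix[4, ] <- mix[3, ]
  for (b in 1:11) {
    noise <- fld(paste0("pheno_noise", b), range_m = rng / 3, sill = 0.02)
    v <- mix[b, 1] * lat[[1]] + mix[b, 2] * lat[[2]] + mix[b, 3] * lat[[3]] +
      noise$values
    layers[[sprintf("pheno_%02d", b)]] <- raster_grid(v, 0, nr * cell, cell)
  }

  # 5 climate bands generated at 960 m then resampled down to the grain;
  # annual mean temperature follows the lapse rate on coarse elevation
  coarse_cell <- 960
  cnr <- max(4L, as.integer(ceiling(nr * cell / coarse_cell)))
  cnc <- max(4L, as.integer(ceiling(nc * cell / coarse_cell)))
  clim_names <- c("temp_mean", "temp_seasonality", "temp_range",
                  "precip_annual", "precip_seasonality")
  elev_coarse <- bilinear_resample(elevation, coarse_cell)
  for (i in seq_along(clim_names)) {
    cf <- gaussian_field(cnr, cnc, coarse_cell, range_m = 6 * coarse_cell,
                         sill = 1, seed = derive_seed(sd0, "clim", i))
    v <- cf$values
    if (clim_names[i] == "temp_mean") {
      ec <- elev_coarse$values
      ec <- ec[seq_len(min(nrow(ec), cnr)), seq_len(min(ncol(ec), cnc)), drop = FALSE]
      vv <- v[seq_len(nrow(ec)), seq_len(ncol(ec)), drop = FALSE]
      # degrees C * 10, 6.5 C/km lapse rate on the coarse DEM plus local field
      v[seq_len(nrow(ec)), seq_len(ncol(ec))] <- 220 - 0.065 * ec + 8 * vv
    }
    cr <- raster_grid(v, 0, cnr * coarse_cell, coarse_cell)
    fine <- bilinear_resample(cr, cell)
    fv <- fine$values[seq_len(nr), seq_len(nc), drop = FALSE]
    if (nrow(fv) < nr || ncol(fv) < nc) { # pad by edge replication if short
      fv <- fv[pmin(seq_len(nr), nrow(fv)), pmin(seq_len(nc), ncol(fv)), drop = FALSE]
    }
    layers[[clim_names[i]]] <- raster_grid(fv, 0, nr * cell, cell)
  }

  reg <- matrix(1L, nr, nc)
  if (config$n_regions == 2L) {
    reg[, seq_len(nc %/% 2)] <- 1L
    reg[, (nc %/% 2 + 1L):nc] <- 2L
  } else if (config$n_regions == 4L) {
    top <- seq_len(nr %/% 2); left <- seq_len(nc %/% 2)
    reg[top, left] <- 1L
    reg[top, -left] <- 2L
    reg[-top, left] <- 3L
    reg[-top, -left] <- 4L
  }
  regions <- raster_grid(reg + 0, 0, nr * cell, cell)

  list(stack = predictor_stack("landscape", layers, grain = cell),
       regions = regions, features = feats, config = config)
}

#' True habitat suitability of a synthetic landscape
#'
#' Applies the configured per-region response on standardized predictors:
#' `suitability = invlogit(intercept_r + sum_v a_{r,v} z_v + b_{r,v} z_v^2)`,
#' where `z_v` is the predictor standardized over the valid landscape cells
#' and `r` the region of the cell.
#'
#' @param landscape Result of [make_landscape()] (or a list with `stack`,
#'   `regions`, `config`).
#' @param config Optional [truth_config()] overriding `landscape$config`.
#' @return A [raster_grid()] with values in `(0, 1)`.
#' @export
true_suitability <- function(landscape, config = NULL) {
  config <- config %||% landscape$config
  st <- landscape$stack
  reg <- landscape$regions$values
  d <- dim(reg)
  lin <- matrix(0, d[1], d[2])
  vars <- unique(unlist(lapply(config$coefficients, names)))
  miss <- setdiff(vars, names(st$layers))
  if (length(miss) > 0L)
    stop("coefficient variable(s) missing from the stack: ",
         paste(miss, collapse = ", "))
  z <- lapply(st$layers[vars], function(r) {
    v <- r$values
    mu <- mean(v, na.rm = TRUE); sd <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sd) || sd == 0) sd <- 1
    (v - mu) / sd
  })
  eta <- matrix(0, d[1], d[2])
  for (rid in seq_len(config$n_regions)) {
    co <- config$coefficients[[as.character(rid)]]
    m <- reg == rid
    acc <- matrix(config$intercepts[rid], d[1], d[2])
    for (v in names(co)) {
      acc <- acc + co[[v]][1] * z[[v]] + co[[v]][2] * z[[v]]^2
    }
    eta[m] <- acc[m]
  }
  raster_grid(.invlogit(eta), st$layers[[1]]$x0, st$layers[[1]]$y0,
              st$layers[[1]]$cell)
}

#' Survey design for presence sampling
#'
#' Emulates a transect-based sign survey: the landscape is tiled by square
#' survey cells (default edge 1414 m, approximating 2 km^2 cells), each cell
#' is surveyed, and the number of detections in a cell is Poisson with mean
#' `detection_scale` times the cell's mean true suitability.
#'
#' @param transect_cell Survey cell edge (m), at least the landscape cell.
#' @param detection_scale Expected detections per survey cell at suitability 1.
#' @param seed Integer seed.
#' @return An object of class `"survey_design"`.
#' @export
survey_design <- function(transect_cell = 1414, detection_scale = 5, seed = 1) {
  if (transect_cell <= 0 || detection_scale <= 0)
    stop("'transect_cell' and 'detection_scale' must be positive")
  structure(list(transect_cell = transect_cell,
                 detection_scale = detection_scale, seed = as.integer(seed)),
            class = "survey_design")
}

#' Simulate a presence-sign survey
#'
#' For every survey cell, draws a Poisson number of detections with mean
#' `detection_scale * mean(suitability)` over the cell's valid landscape
#' cells, and places each detection uniformly at random within the survey
#' cell. Deterministic given the design seed.
#'
#' @param suitability A [raster_grid()] with values in `[0, 1]`.
#' @param design A [survey_design()].
#' @return Data frame with columns `x`, `y` (meters).
#' @export
simulate_survey <- function(suitability, design) {
  v <- suitability$values
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]")
  if (design$transect_cell < suitability$cell)
    stop("'transect_cell' must be >= the landscape cell size")
  ext <- raster_extent(suitability)
  tc <- design$transect_cell
  nx <- as.integer(ceiling((ext["xmax"] - ext["xmin"]) / tc))
  ny <- as.integer(ceiling((ext["ymax"] - ext["ymin"]) / tc))
  withr::with_seed(design$seed, {
    xs <- ys <- numeric(0)
    for (iy in seq_len(ny)) {
      for (ix in seq_len(nx)) {
        rect <- c(ext["xmin"] + (ix - 1) * tc,
                  ext["ymax"] - iy * tc,
                  ext["xmin"] + ix * tc,
                  ext["ymax"] - (iy - 1) * tc)
        rect[1] <- max(rect[1], ext["xmin"]); rect[2] <- max(rect[2], ext["ymin"])
        rect[3] <- min(rect[3], ext["xmax"]); rect[4] <- min(rect[4], ext["ymax"])
        mu <- tryCatch(mean(crop_raster(suitability, rect)$values, na.rm = TRUE),
                       error = function(e) NA_real_)
        if (!is.finite(mu) || mu <= 0) next
        n <- stats::rpois(1, design$detection_scale * mu)
        if (n > 0) {
          xs <- c(xs, stats::runif(n, rect[1], rect[3]))
          ys <- c(ys, stats::runif(n, rect[2], rect[4]))
        }
      }
    }
    data.frame(x = xs, y = ys)
  })
}

#' Write the truth record of a synthetic landscape as JSON
#'
#' @param landscape Result of [make_landscape()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_record <- function(landscape, path) {
  cfg <- landscape$config
  rec <- list(shape = cfg$shape, cell = cfg$cell,
              field_range = cfg$field_range, n_regions = cfg$n_regions,
              coefficients = cfg$coefficients, intercepts = cfg$intercepts,
              seed = cfg$seed)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
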