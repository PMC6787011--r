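#' Aggregate a raster to a coarser grain
#'
#' Blocks of `factor x factor` input cells are collapsed into one output cell
#' using the block mean or median over valid cells. Trailing rows/columns that
#' do not fill a complete block are dropped, and blocks that are entirely
#' nodata become nodata. With `stat = "mean"` on a fully valid raster whose
#' dimensions are exact multiples of `factor`, the global mean is preserved
#' exactly and aggregation by 2 twice equals aggregation by 4.
#'
#' @param r A [raster_grid()].
#' @param factor Positive integer block edge (output cell = `r$cell * factor`).
#' @param stat `"mean"` or `"median"`.
#' @return A [raster_grid()] at the coarser grain.
#' @export
aggregate_raster <- function(r, factor, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("'factor' must be a positive integer")
  d <- dim(r$values)
  if (d[1] < factor || d[2] < factor)
    stop("raster smaller than one aggregation block")
  if (factor == 1L) return(r)
  nr2 <- d[1] %/% factor
  nc2 <- d[2] %/% factor
  v <- r$values[seq_len(nr2 * factor), seq_len(nc2 * factor), drop = FALSE]
  # regroup into (block cells) x nr2 x nc2 and reduce over the first dim
  arr <- array(v, dim = c(factor, nr2, factor, nc2))
  arr <- aperm(arr, c(1, 3, 2, 4))
  dim(arr) <- c(factor * factor, nr2, nc2)
  if (stat == "mean") {
    out <- colMeans(arr, na.rm = TRUE, dims = 1)
  } else {
    out <- apply(arr, c(2, 3), stats::median, na.rm = TRUE)
  }
  out[!is.finite(out)] <- NA_real_
  raster_grid(matrix(out, nrow = nr2, ncol = nc2),
              x0 = r$x0, y0 = r$y0, cell = r$cell * factor, nodata = r$nodata)
}

#' Resample a raster by bilinear interpolation
#'
#' Builds an output grid sharing the input's top-left anchor with
#' `round(extent / target_cell)` cells per side (the footprint is preserved to
#' within one output cell), and interpolates each output cell center from the
#' four surrounding input cell centers. Centers outside the input center
#' lattice clamp to the nearest valid row/column, so constant rasters are
#' reproduced exactly and affine surfaces are reproduced exactly in the
#' interior. Nodata neighbors are dropped and the remaining weights
#' renormalized; a cell with no valid neighbor is nodata.
#'
#' @param r A [raster_grid()].
#' @param target_cell Output cell size (m), `> 0`.
#' @return A [raster_grid()] at `target_cell`.
#' @export
bilinear_resample <- function(r, target_cell) {
  if (!is.numeric(target_cell) || target_cell <= 0)
    stop("'target_cell' must be positive")
  if (all(is.na(r$values))) stop("cannot resample an all-nodata raster")
  d <- dim(r$values)
  nro <- max(1L, as.integer(round(d[1] * r$cell / target_cell)))
  nco <- max(1L, as.integer(round(d[2] * r$cell / target_cell)))
  # output cell centers in input fractional row/col coordinates
  xo <- ((seq_len(nco) - 0.5) * target_cell) / r$cell + 0.5
  yo <- ((seq_len(nro) - 0.5) * target_cell) / r$cell + 0.5
  interp_axis <- function(t, n) {
    t <- pmin(pmax(t, 1), n)           # clamp to the center lattice
    i0 <- pmin(floor(t), n - 1L)
    if (n == 1L) i0 <- rep(1L, length(t))
    w <- t - i0
    list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1L, n)), w = w)
  }
  ax <- interp_axis(xo, d[2])
  ay <- interp_axis(yo, d[1])
  v <- r$values
  out <- matrix(NA_real_, nro, nco)
  for (j in seq_len(nco)) {
    c0 <- ax$i0[j]; c1 <- ax$i1[j]; wx <- ax$w[j]
    q00 <- v[ay$i0, c0]; q01 <- v[ay$i0, c1]
    q10 <- v[ay$i1, c0]; q11 <- v[ay$i1, c1]
    w00 <- (1 - ay$w) * (1 - wx); w01 <- (1 - ay$w) * wx
    w10 <- ay$w * (1 - wx);       w11 <- ay$w * wx
    qs <- cbind(q00, q01, q10, q11)
    ws <- cbind(w00, w01, w10, w11)
    ws[is.na(qs)] <- 0
    tot <- rowSums(ws)
    num <- rowSums(qs * ws, na.rm = TRUE)
    out[, j] <- ifelse(tot > 0, num / tot, NA_real_)
  }
  raster_grid(out, x0 = r$x0, y0 = r$y0, cell = target_cell, nodata = r$nodata)
}

#' Slope from a digital elevation model
#'
#' Horn's 3x3 finite-difference stencil: with the window labelled
#' `a b c / d e f / g h i` (row-major, north up),
#' `dz/dx = ((c + 2f + i) - (a + 2d + g)) / (8 cell)` and
#' `dz/dy = ((g + 2h + i) - (a + 2b + c)) / (8 cell)`; the slope is
#' `atan(sqrt(dzdx^2 + dzdy^2))` in degrees. Border cells use edge
#' replication; any window touching nodata yields nodata.
#'
#' @param dem A [raster_grid()] of elevations (m), at least 3x3.
#' @return A [raster_grid()] of slopes in degrees, in `[0, 90)`.
#' @export
slope_from_dem <- function(dem) {
  d <- dim(dem$values)
  if (d[1] < 3L || d[2] < 3L) stop("DEM must be at least 3x3")
  v <- dem$values
  # pad by edge replication
  rp <- c(1L, seq_len(d[1]), d[1])
  cp <- c(1L, seq_len(d[2]), d[2])
  p <- v[rp, cp, drop = FALSE]
  sh <- function(dr, dc) p[seq_len(d[1]) + 1L + dr, seq_len(d[2]) + 1L + dc]
  a <- sh(-1L, -1L); b <- sh(-1L, 0L); cc <- sh(-1L, 1L)
  dd <- sh(0L, -1L);                    f <- sh(0L, 1L)
  g <- sh(1L, -1L);  h <- sh(1L, 0L);   i <- sh(1L, 1L)
  dzdx <- ((cc + 2 * f + i) - (a + 2 * dd + g)) / (8 * dem$cell)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * dem$cell)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  raster_grid(slope, x0 = dem$x0, y0 = dem$y0, cell = dem$cell,
              nodata = dem$nodata)
}

# distance from points (px, py) to segment (x1,y1)-(x2,y2), vectorized on points
.dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
  sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
}

#' Euclidean distance to the nearest feature
#'
#' Computes, for every cell center of the template grid, the planar Euclidean
#' distance to the nearest feature. Features are points (a 1-row matrix) or
#' polylines (an n x 2 matrix of vertices traversed in order). A cell whose
#' center lies on a feature has distance 0; nodata cells of the template stay
#' nodata.
#'
#' @param features A list of numeric matrices with columns `x, y` (meters).
#' @param grid Template [raster_grid()] (values used only for the nodata mask).
#' @return A [raster_grid()] of distances in meters.
#' @export
distance_raster <- function(features, grid) {
  if (!is.list(features) || length(features) == 0L)
    stop("'features' must be a non-empty list of coordinate matrices")
  ctr <- cell_centers(grid)
  dmin <- rep(Inf, nrow(ctr))
  for (f in features) {
    f <- as.matrix(f)
    if (ncol(f) != 2L || nrow(f) < 1L)
      stop("each feature must be an n x 2 coordinate matrix")
    if (nrow(f) == 1L) {
      dmin <- pmin(dmin, sqrt((ctr$x - f[1, 1])^2 + (ctr$y - f[1, 2])^2))
    } else {
      for (s in seq_len(nrow(f) - 1L)) {
        dmin <- pmin(dmin, .dist_point_segment(ctr$x, ctr$y,
                                               f[s, 1], f[s, 2],
                                               f[s + 1L, 1], f[s + 1L, 2]))
      }
    }
  }
  d <- dim(grid$values)
  out <- matrix(NA_real_, d[1], d[2])
  out[cbind(ctr$row, ctr$col)] <- dmin
  out[is.na(grid$values)] <- NA_real_
  raster_grid(out, x0 = grid$x0, y0 = grid$y0, cell = grid$cell,
              nodata = grid$nodata)
}

#' Rasterize presence points onto a grid
#'
#' Bins presence points into the template's cells (half-open convention) and
#' returns both the per-cell counts and the binary presence mask. Prevalence
#' is the number of presence cells divided by the number of valid (non-nodata)
#' template cells. Points outside the footprint are dropped with a warning.
#'
#' @param points Data frame or matrix with columns `x`, `y` (meters).
#' @param grid Template [raster_grid()].
#' @return An object of class `"presence_grid"`: list with `mask` and `counts`
#'   rasters, `n_points`, `n_cells`, and `prevalence`.
#' @export
rasterize_presence <- function(points, grid) {
  pts <- as.data.frame(points)
  d <- dim(grid$values)
  n_valid <- sum(!is.na(grid$values))
  counts <- matrix(0, d[1], d[2])
  if (nrow(pts) > 0L) {
    idx <- point_to_cell(grid, pts$x, pts$y)
    if (any(!idx$inside))
      warning(sum(!idx$inside), " presence point(s) outside the grid dropped")
    idx <- idx[idx$inside, , drop = FALSE]
    if (nrow(idx) > 0L) {
      tab <- table(factor(idx$row, levels = seq_len(d[1])),
                   factor(idx$col, levels = seq_len(d[2])))
      counts <- matrix(as.numeric(tab), d[1], d[2])
    }
  }
  counts[is.na(grid$values)] <- NA_real_
  mask <- (counts > 0) * 1
  n_cells <- sum(mask == 1, na.rm = TRUE)
  structure(
    list(mask = raster_grid(mask, grid$x0, grid$y0, grid$cell, grid$nodata),
         counts = raster_grid(counts, grid$x0, grid$y0, grid$cell, grid$nodata),
         n_points = sum(counts, na.rm = TRUE),
         n_cells = n_cells,
         prevalence = if (n_valid > 0) n_cells / n_valid else NA_real_),
    class = "presence_grid"
  )
}

#' @export
print.presence_grid <- function(x, ...) {
  cat(sprintf("<presence_grid> %d points in %d cells (prevalence %.3g)\n",
              x$n_points, x$n_cells, x$prevalence))
  invisible(x)
}

#' Reduce a correlated band set to principal components
#'
#' Centers and scales every band to unit variance (correlation-matrix PCA,
#' appropriate for bands in mixed units), decomposes over the cells that are
#' valid in all bands, and keeps the smallest number of leading components
#' whose cumulative explained variance reaches `variance_threshold`, capped at
#' `max_components`. Constant bands are dropped with a warning.
#'
#' @param stack A [predictor_stack()] or named list of aligned rasters.
#' @param variance_threshold Fraction in `(0, 1]` of variance to retain.
#' @param max_components Upper bound on retained components (default 5).
#' @param prefix Name prefix for component layers.
#' @return A [predictor_stack()] of component score rasters, with attributes
#'   `explained` (per-component variance fractions) and `loadings`.
#' @export
pca_reduce <- function(stack, variance_threshold = 0.99, max_components = 5,
                       prefix = "pc") {
  layers <- if (inherits(stack, "predictor_stack")) stack$layers else stack
  if (length(layers) < 2L) stop("need at least 2 bands for PCA")
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("'variance_threshold' must be in (0, 1]")
  tmpl <- layers[[1]]
  mats <- lapply(layers, function(r) as.vector(r$values))
  X <- do.call(cbind, mats)
  colnames(X) <- names(layers)
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  const <- !is.finite(sds) | sds == 0
  if (all(const)) stop("all bands are constant; PCA undefined")
  if (any(const)) {
    warning("dropping constant band(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  ok <- stats::complete.cases(X)
  if (sum(ok) < 3L) stop("too few jointly valid cells for PCA")
  pc <- stats::prcomp(X[ok, , drop = FALSE], center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(expl) >= variance_threshold - 1e-12)[1]
  if (is.na(k)) k <- length(expl)
  k <- min(k, max_components, length(expl))
  d <- dim(tmpl$values)
  out <- vector("list", k)
  for (j in seq_len(k)) {
    m <- matrix(NA_real_, d[1], d[2])
    m[ok] <- pc$x[, j]
    out[[j]] <- raster_grid(m, tmpl$x0, tmpl$y0, tmpl$cell, tmpl$nodata)
  }
  names(out) <- paste0(prefix, seq_len(k))
  st <- predictor_stack("pca", out, grain = tmpl$cell)
  attr(st, "explained") <- expl[seq_len(k)]
  attr(st, "loadings") <- pc$rotation[, seq_len(k), drop = FALSE]
  st
}

#' Named stack of grid-aligned predictor rasters
#'
#' @param name Variable-set label (e.g. `"base"`, `"base_pheno"`,
#'   `"base_pheno_clim"`).
#' @param layers Named list of [raster_grid()] objects sharing origin, cell
#'   size and shape exactly.
#' @param grain Cell size in meters; defaults to the layers' cell.
#' @return An object of class `"predictor_stack"`.
#' @export
predictor_stack <- function(name, layers, grain = NULL) {
  if (length(layers) == 0L) stop("empty layer list")
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("all layers must be named")
  ref <- layers[[1]]
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!is_raster(l)) stop("layer '", nm, "' is not a raster_grid")
    if (!identical(dim(l$values), dim(ref$values)) ||
        l$x0 != ref$x0 || l$y0 != ref$y0 || l$cell != ref$cell)
      stop("layer '", nm, "' is not aligned with the first layer")
  }
  if (is.null(grain)) grain <- ref$cell
  structure(list(name = name, layers = layers, grain = grain),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> '%s' @ %g m: %s\n", x$name, x$grain,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Extract stack values at points as a data frame
#'
#' @param stack A [predictor_stack()].
#' @param x,y Point coordinates (meters).
#' @return Data frame with one column per layer.
#' @export
stack_values <- function(stack, x, y) {
  out <- lapply(stack$layers, extract_values, x = x, y = y)
  as.data.frame(out)
}

#' Crop every layer of a stack to a rectangle
#'
#' @param stack A [predictor_stack()].
#' @param rect Numeric `c(xmin, ymin, xmax, ymax)`.
#' @return A [predictor_stack()].
#' @export
crop_stack <- function(stack, rect) {
  predictor_stack(stack$name, lapply(stack$layers, crop_raster, rect = rect),
                  grain = stack$grain)
}
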