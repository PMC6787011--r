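#' Planar raster grid
#'
#' A minimal single-band raster: a numeric matrix with a top-left anchor and a
#' square cell size, all in planar meters. Row 1 is the northmost row and the
#' y coordinate decreases with the row index. Cells are half-open
#' `[edge, edge + cell)`, so a point `(x, y)` falls in column
#' `floor((x - x0)/cell) + 1` and row `floor((y0 - y)/cell) + 1`. Missing cells
#' are stored as `NA`; the `nodata` field only records the sentinel used when
#' the grid is written to disk.
#'
#' @param values Numeric matrix, row-major north-to-south. Nodata cells are `NA`.
#' @param x0,y0 Real-world coordinates (m) of the grid's top-left corner.
#' @param cell Cell edge length in meters (square cells), `> 0`.
#' @param nodata Sentinel written for `NA` cells by [write_esri_ascii()].
#'
#' @return An object of class `"raster_grid"`.
#' @seealso [read_esri_ascii()], [aggregate_raster()], [bilinear_resample()]
#' @export
raster_grid <- function(values, x0 = 0, y0 = nrow(values) * cell, cell = 30,
                        nodata = -9999) {
  if (!is.matrix(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("'values' must be a non-empty matrix")
  if (!is.numeric(cell) || length(cell) != 1L || cell <= 0)
    stop("'cell' must be a single positive number")
  storage.mode(values) <- "double"
  structure(
    list(values = values, x0 = as.numeric(x0), y0 = as.numeric(y0),
         cell = as.numeric(cell), nodata = as.numeric(nodata)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, cell = %g m\n", nrow(v), ncol(v), x$cell))
  cat(sprintf("  origin (top-left): (%g, %g)\n", x$x0, x$y0))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  else cat("  values: all nodata\n")
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

is_raster <- function(x) inherits(x, "raster_grid")

#' Raster footprint
#'
#' @param r A [raster_grid()].
#' @return Named numeric vector `xmin, ymin, xmax, ymax` (meters).
#' @export
raster_extent <- function(r) {
  d <- dim(r$values)
  c(xmin = r$x0, ymin = r$y0 - d[1] * r$cell,
    xmax = r$x0 + d[2] * r$cell, ymax = r$y0)
}

#' Cell-center coordinates
#'
#' @param r A [raster_grid()].
#' @param rows,cols Optional integer vectors (paired) selecting cells; default
#'   all cells in column-major order.
#' @return Data frame with columns `x`, `y`, `row`, `col`.
#' @export
cell_centers <- function(r, rows = NULL, cols = NULL) {
  d <- dim(r$values)
  if (is.null(rows)) {
    rows <- rep(seq_len(d[1]), times = d[2])
    cols <- rep(seq_len(d[2]), each = d[1])
  }
  data.frame(x = r$x0 + (cols - 0.5) * r$cell,
             y = r$y0 - (rows - 0.5) * r$cell,
             row = rows, col = cols)
}

#' Map points to raster cells
#'
#' Half-open cell convention: `col = floor((x - x0)/cell) + 1`,
#' `row = floor((y0 - y)/cell) + 1`.
#'
#' @param r A [raster_grid()].
#' @param x,y Point coordinates (meters).
#' @return Data frame with `row`, `col` and logical `inside`.
#' @export
point_to_cell <- function(r, x, y) {
  d <- dim(r$values)
  col <- floor((x - r$x0) / r$cell) + 1
  row <- floor((r$y0 - y) / r$cell) + 1
  inside <- col >= 1 & col <= d[2] & row >= 1 & row <= d[1]
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Extract raster values at points
#'
#' @param r A [raster_grid()].
#' @param x,y Point coordinates (meters).
#' @return Numeric vector; `NA` for points outside the grid or on nodata cells.
#' @export
extract_values <- function(r, x, y) {
  idx <- point_to_cell(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- idx$inside
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Crop a raster to a rectangle
#'
#' Keeps the cells whose centers fall inside `rect` (half-open on the max
#' edges, so abutting rectangles partition cells).
#'
#' @param r A [raster_grid()].
#' @param rect Numeric `c(xmin, ymin, xmax, ymax)` in meters.
#' @return A [raster_grid()] covering the selected cells.
#' @export
crop_raster <- function(r, rect) {
  d <- dim(r$values)
  cx <- r$x0 + (seq_len(d[2]) - 0.5) * r$cell
  cy <- r$y0 - (seq_len(d[1]) - 0.5) * r$cell
  keep_c <- which(cx >= rect[1] & cx < rect[3])
  keep_r <- which(cy >= rect[2] & cy < rect[4])
  if (length(keep_c) == 0L || length(keep_r) == 0L)
    stop("crop rectangle contains no cell centers")
  raster_grid(r$values[keep_r, keep_c, drop = FALSE],
              x0 = r$x0 + (min(keep_c) - 1) * r$cell,
              y0 = r$y0 - (min(keep_r) - 1) * r$cell,
              cell = r$cell, nodata = r$nodata)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Emits the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows north to south.
#'
#' @param r A [raster_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(r, path) {
  d <- dim(r$values)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", r$x0),
    sprintf("yllcorner %.10g", r$y0 - d[1] * r$cell),
    sprintf("cellsize %.10g", r$cell),
    sprintf("NODATA_value %.10g", r$nodata)
  ), con)
  v <- r$values
  v[is.na(v)] <- r$nodata
  for (i in seq_len(d[1]))
    writeLines(paste(formatC(v[i, ], format = "g", digits = 15), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path to a `.asc` grid.
#' @return A [raster_grid()]; sentinel cells become `NA`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing ESRI ASCII header fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("ESRI ASCII body has ", length(vals), " values, expected ",
         hdr$nrows * hdr$ncols)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, x0 = hdr$xllcorner,
              y0 = hdr$yllcorner + hdr$nrows * hdr$cellsize,
              cell = hdr$cellsize, nodata = nodata)
}
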