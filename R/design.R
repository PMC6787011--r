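#' Rectangular study-extent replicate
#'
#' One replicate of a total-extent level: level 1 are small gridded blocks,
#' level 2 their non-overlapping buffers, level 3 the (synthetic) region
#' extents and level 4 the full domain. `parent` links a nested extent to the
#' label of the extent containing it.
#'
#' @param level Integer 1-4.
#' @param replicate_id Character label, unique within a level.
#' @param rect Numeric `c(xmin, ymin, xmax, ymax)` (meters).
#' @param parent Label of the containing extent, or `NA`.
#' @param n_presence Optional presence-point count recorded at construction.
#' @return An object of class `"extent_spec"` with an `area_km2` field.
#' @export
extent_spec <- function(level, replicate_id, rect, parent = NA_character_,
                        n_presence = NA_integer_) {
  rect <- as.numeric(rect)
  if (length(rect) != 4L || rect[3] <= rect[1] || rect[4] <= rect[2])
    stop("'rect' must be c(xmin, ymin, xmax, ymax) with positive width/height")
  structure(list(level = as.integer(level),
                 replicate_id = as.character(replicate_id),
                 rect = rect, parent = as.character(parent),
                 n_presence = n_presence,
                 area_km2 = (rect[3] - rect[1]) * (rect[4] - rect[2]) / 1e6),
            class = "extent_spec")
}

#' @export
print.extent_spec <- function(x, ...) {
  cat(sprintf("<extent_spec> level %d '%s': [%g, %g] x [%g, %g] (%.2f km^2)\n",
              x$level, x$replicate_id, x$rect[1], x$rect[3], x$rect[2],
              x$rect[4], x$area_km2))
  invisible(x)
}

rects_overlap <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

rect_contains <- function(outer, inner, tol = 1e-9) {
  outer[1] <= inner[1] + tol && outer[2] <= inner[2] + tol &&
    outer[3] >= inner[3] - tol && outer[4] >= inner[4] - tol
}

count_in_rect <- function(points, rect) {
  sum(points$x >= rect[1] & points$x < rect[3] &
        points$y >= rect[2] & points$y < rect[4])
}

#' Grid a domain into candidate level-1 blocks
#'
#' Tiles the domain with square blocks of the requested area, anchored at the
#' domain's top-left corner (partial edge blocks are not formed), and keeps
#' the blocks containing at least `min_presence` presence points (half-open
#' membership on the max edges).
#'
#' @param domain Numeric `c(xmin, ymin, xmax, ymax)` (meters).
#' @param presences Data frame with columns `x`, `y`.
#' @param block_area_km2 Block area in km^2 (side `sqrt(area)`).
#' @param min_presence Minimum presence points for a block to be retained.
#' @return List of [extent_spec()] objects (level 1) with `n_presence` filled.
#' @export
grid_blocks <- function(domain, presences, block_area_km2 = 50,
                        min_presence = 20) {
  side <- sqrt(block_area_km2 * 1e6)
  w <- domain[3] - domain[1]; h <- domain[4] - domain[2]
  if (side > w + 1e-9 || side > h + 1e-9)
    stop("block larger than the domain")
  nx <- floor(w / side + 1e-9); ny <- floor(h / side + 1e-9)
  out <- list()
  k <- 0L
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      rect <- c(domain[1] + (ix - 1) * side, domain[4] - iy * side,
                domain[1] + ix * side, domain[4] - (iy - 1) * side)
      n <- count_in_rect(presences, rect)
      if (n >= min_presence) {
        k <- k + 1L
        out[[k]] <- extent_spec(1L, sprintf("L1_%02d", k), rect,
                                n_presence = n)
      }
    }
  }
  out
}

#' Buffer blocks into non-overlapping larger extents
#'
#' Repeatedly draws a random retained block (seeded), expands it to a
#' concentric square of the target area clipped to the domain, and accepts it
#' if it overlaps no previously accepted buffer, until `n_target` buffers are
#' accepted or the candidates are exhausted (then fewer are returned, with a
#' warning). Each accepted extent records its seed block as nested child via
#' the block's `parent` update in the returned `blocks` element.
#'
#' @param blocks List of level-1 [extent_spec()] from [grid_blocks()].
#' @param domain Numeric `c(xmin, ymin, xmax, ymax)`.
#' @param target_area_km2 Buffer area in km^2 (must exceed the block area).
#' @param n_target Number of buffers wanted.
#' @param seed Integer seed for the random block order.
#' @return List with `buffers` (level-2 [extent_spec()] list, each carrying a
#'   `child` label) and `blocks` (the input blocks with `parent` set for the
#'   seeded ones).
#' @export
buffer_nonoverlapping <- function(blocks, domain, target_area_km2 = 500,
                                  n_target = 9, seed = 1) {
  if (length(blocks) == 0L) return(list(buffers = list(), blocks = blocks))
  if (target_area_km2 <= blocks[[1]]$area_km2)
    stop("'target_area_km2' must exceed the block area")
  if (n_target < 1L) stop("'n_target' must be >= 1")
  side <- sqrt(target_area_km2 * 1e6)
  order <- withr::with_seed(seed, sample(seq_along(blocks)))
  buffers <- list()
  for (i in order) {
    b <- blocks[[i]]
    cx <- mean(b$rect[c(1, 3)]); cy <- mean(b$rect[c(2, 4)])
    rect <- c(cx - side / 2, cy - side / 2, cx + side / 2, cy + side / 2)
    rect <- c(max(rect[1], domain[1]), max(rect[2], domain[2]),
              min(rect[3], domain[3]), min(rect[4], domain[4]))
    ok <- !any(vapply(buffers, function(bf) rects_overlap(bf$rect, rect),
                      logical(1)))
    if (ok) {
      id <- sprintf("L2_%02d", length(buffers) + 1L)
      bf <- extent_spec(2L, id, rect)
      bf$child <- b$replicate_id
      buffers[[length(buffers) + 1L]] <- bf
      blocks[[i]]$parent <- id
    }
    if (length(buffers) >= n_target) break
  }
  if (length(buffers) < n_target)
    warning("only ", length(buffers), " of ", n_target,
            " non-overlapping buffers could be placed")
  list(buffers = buffers, blocks = blocks)
}

#' Sample background points inside an extent
#'
#' Eligible cells are the valid (non-nodata) template cells whose centers
#' fall inside the extent and whose elevation is strictly below `max_elev`
#' (emulating the exclusion of alpine areas above the bamboo line). If there
#' are at most `n` eligible cells, all of their centers are returned; else
#' `n` distinct cells are sampled uniformly without replacement (seeded).
#'
#' @param extent An [extent_spec()].
#' @param template A [raster_grid()] at the working grain (its nodata mask is
#'   honored).
#' @param elevation A [raster_grid()] aligned with `template`.
#' @param n Requested background size (default 10000).
#' @param max_elev Elevation ceiling in meters (default 3600).
#' @param seed Integer seed.
#' @return Data frame with columns `x`, `y` (cell centers).
#' @export
sample_background <- function(extent, template, elevation, n = 10000,
                              max_elev = 3600, seed = 1) {
  if (n < 1L) stop("'n' must be >= 1")
  ctr <- cell_centers(template)
  ok <- !is.na(template$values[cbind(ctr$row, ctr$col)]) &
    ctr$x >= extent$rect[1] & ctr$x < extent$rect[3] &
    ctr$y >= extent$rect[2] & ctr$y < extent$rect[4]
  ev <- extract_values(elevation, ctr$x, ctr$y)
  ok <- ok & !is.na(ev) & ev < max_elev
  idx <- which(ok)
  if (length(idx) == 0L)
    stop("no eligible background cells in extent '", extent$replicate_id, "'")
  if (length(idx) > n)
    idx <- withr::with_seed(seed, sort(sample(idx, n)))
  data.frame(x = ctr$x[idx], y = ctr$y[idx])
}

#' k-fold split of presence records
#'
#' Seeded random permutation split into `k` near-equal disjoint test sets;
#' fold `i` trains on the complement of test set `i`. Test sets partition
#' the indices, so every record is tested exactly once.
#'
#' @param n_points Number of presence records.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `k` lists with `fold_id`, `train_idx`, `test_idx`.
#' @export
kfold_split <- function(n_points, k = 5, seed = 1) {
  if (n_points < k) stop("need at least k = ", k, " points, got ", n_points)
  perm <- withr::with_seed(seed, sample(seq_len(n_points)))
  # fold sizes as even as possible: the first (n %% k) folds get one extra
  sizes <- rep(n_points %/% k, k)
  extra <- n_points %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    test <- sort(perm[starts[i]:stops[i]])
    list(fold_id = i, train_idx = setdiff(seq_len(n_points), test),
         test_idx = test)
  })
}
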