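#' Layered terrain grid
#'
#' A `grid_map` bundles three co-registered rasters on the same R x C grid:
#' `elevation` (meters above sea level), `linear_features` (logical: cells an
#' agent may follow, e.g. trails, streams, shorelines, ridge lines) and
#' `inaccessible` (logical: cells an agent may never occupy, e.g. lake
#' interiors). Positions are `(x = column, y = row)`, 1-based, with y
#' increasing north; a raster cell `(x, y)` is `raster[y, x]`. The two
#' logical layers are kept disjoint: an inaccessible cell is never also a
#' linear feature.
#'
#' @param elevation numeric matrix of elevations (meters).
#' @param feature_masks list of logical matrices to be OR-ed into the linear
#'   feature layer (may be empty).
#' @param inaccessible_masks list of logical matrices to be OR-ed into the
#'   inaccessible layer (may be empty).
#' @param cell_size side of a grid cell in meters; the reference
#'   configuration divides a 20 km extent into 3000 cells (6.67 m).
#' @param origin optional two-vector of map-coordinate origin (geo-transform).
#' @param crs optional coordinate reference tag carried through unchanged.
#' @return an object of class `grid_map`.
#' @examples
#' m <- assemble_map(matrix(0, 5, 5), cell_size = 10)
#' dim(m$elevation)
#' @export
assemble_map <- function(elevation, feature_masks = list(),
                         inaccessible_masks = list(),
                         cell_size = 20000 / 3000, origin = NULL, crs = NULL) {
  stopifnot(is.matrix(elevation), cell_size > 0)
  if (is.matrix(feature_masks)) feature_masks <- list(feature_masks)
  if (is.matrix(inaccessible_masks)) inaccessible_masks <- list(inaccessible_masks)
  dm <- dim(elevation)
  or_masks <- function(masks, what) {
    out <- matrix(FALSE, dm[1], dm[2])
    for (m in masks) {
      if (!identical(dim(m), dm))
        stop(what, " mask shape ", paste(dim(m), collapse = "x"),
             " does not match elevation ", paste(dm, collapse = "x"))
      out <- out | m
    }
    out
  }
  features <- or_masks(feature_masks, "feature")
  inaccessible <- or_masks(inaccessible_masks, "inaccessible")
  # interiors win: an inaccessible cell cannot be followed as a feature
  features[inaccessible] <- FALSE
  structure(list(elevation = elevation, linear_features = features,
                 inaccessible = inaccessible, cell_size = cell_size,
                 origin = origin, crs = crs),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  dm <- dim(x$elevation)
  cat(sprintf("<grid_map> %d x %d cells, %.2f m/cell (%.1f x %.1f km)\n",
              dm[1], dm[2], x$cell_size,
              dm[2] * x$cell_size / 1000, dm[1] * x$cell_size / 1000))
  cat(sprintf("  elevation: %.1f..%.1f m | feature cells: %d | inaccessible: %d\n",
              min(x$elevation), max(x$elevation),
              sum(x$linear_features), sum(x$inaccessible)))
  invisible(x)
}

#' Map geometry helpers
#'
#' `map_dims()` returns `c(rows, cols)`; `map_center()` the central cell as
#' `(x, y)` (for the reference 3000 x 3000 grid this is cell (1500, 1500));
#' `is_accessible()` whether a cell lies inside the grid and outside the
#' inaccessible layer.
#'
#' @param map a `grid_map`.
#' @param cell integer `(x, y)` cell.
#' @export
map_dims <- function(map) dim(map$elevation)

#' @rdname map_dims
#' @export
map_center <- function(map) {
  dm <- map_dims(map)
  c(floor((dm[2] + 1) / 2), floor((dm[1] + 1) / 2))
}

#' @rdname map_dims
#' @export
is_accessible <- function(map, cell) {
  dm <- map_dims(map)
  x <- cell[1]; y <- cell[2]
  x >= 1 && x <= dm[2] && y >= 1 && y <= dm[1] && !map$inaccessible[y, x]
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# derivative-of-Gaussian kernel, normalized so a unit ramp responds with
# magnitude 1 (sign depends on convolution orientation; magnitude is used)
dgaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  d <- -x * exp(-x^2 / (2 * sigma^2))
  d / sum(-x * d) * -1
}

filter_replicate <- function(m, kernel) {
  EBImage::filter2(m, kernel, boundary = "replicate")
}

#' Gradient magnitude of an elevation raster
#'
#' Computes the two derivative-of-Gaussian responses of the elevation field,
#' takes their Euclidean norm and smooths the result with a Gaussian of the
#' same scale. The response is calibrated so a planar ramp of slope s (meters
#' per cell) yields magnitude s on interior cells.
#'
#' @param elevation numeric matrix (meters); all values must be finite.
#' @param sigma smoothing scale in cells (> 0).
#' @return nonnegative numeric matrix of the same shape.
#' @export
gradient_magnitude <- function(elevation, sigma = 3) {
  stopifnot(is.matrix(elevation), sigma > 0)
  bad <- which(!is.finite(elevation), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    shown <- head(apply(bad, 1, function(rc)
      sprintf("(x=%d, y=%d)", rc[2], rc[1])), 5)
    stop("elevation contains non-finite values at cells: ",
         paste(shown, collapse = ", "),
         if (nrow(bad) > 5) sprintf(" and %d more", nrow(bad) - 5) else "")
  }
  g <- gaussian_kernel_1d(sigma)
  d <- dgaussian_kernel_1d(sigma)
  gx <- filter_replicate(elevation, outer(g, d))   # d/dx (columns)
  gy <- filter_replicate(elevation, outer(d, g))   # d/dy (rows)
  mag <- sqrt(gx^2 + gy^2)
  filter_replicate(mag, outer(g, g))
}

#' Canny extraction of ridge and drainage lines
#'
#' Runs Canny edge detection on a scalar field (normally the smoothed
#' gradient-magnitude raster of the elevation): derivative-of-Gaussian
#' gradients, non-maximum suppression across the gradient direction, and
#' hysteresis thresholding that keeps weak edge cells only when 8-connected
#' to a strong one. Edges of the gradient-magnitude field trace the flanks of
#' steep bands and the crest/drainage lines where the magnitude peaks or
#' vanishes.
#'
#' @param field numeric matrix (e.g. output of [gradient_magnitude()]).
#' @param canny_sigma Gaussian scale (cells) for the edge gradients.
#' @param low_thresh,high_thresh hysteresis thresholds on the edge-gradient
#'   magnitude, `0 <= low < high`; when `NULL` they default to the 70th and
#'   90th percentiles of the nonzero edge-gradient magnitudes, adapting to
#'   the relief scale.
#' @return logical matrix marking edge cells; a constant field yields an
#'   empty mask.
#' @export
detect_elevation_linear_features <- function(field, canny_sigma = 3,
                                             low_thresh = NULL,
                                             high_thresh = NULL) {
  stopifnot(is.matrix(field), canny_sigma > 0)
  if (max(field) == min(field)) return(matrix(FALSE, nrow(field), ncol(field)))
  g <- gaussian_kernel_1d(canny_sigma)
  d <- dgaussian_kernel_1d(canny_sigma)
  gx <- filter_replicate(field, outer(g, d))
  gy <- filter_replicate(field, outer(d, g))
  mag <- sqrt(gx^2 + gy^2)
  if (is.null(low_thresh) || is.null(high_thresh)) {
    pos <- mag[mag > 0]
    if (length(pos) == 0) return(matrix(FALSE, nrow(field), ncol(field)))
    q <- quantile(pos, c(0.7, 0.9), names = FALSE)
    if (is.null(low_thresh)) low_thresh <- q[1]
    if (is.null(high_thresh)) high_thresh <- q[2]
  }
  if (!(low_thresh >= 0 && low_thresh < high_thresh))
    stop("thresholds must satisfy 0 <= low < high")
  nms <- canny_nms(mag, gx, gy)
  weak <- nms >= low_thresh
  strong <- nms >= high_thresh
  if (!any(strong)) return(matrix(FALSE, nrow(field), ncol(field)))
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  matrix(lab %in% keep, nrow(field), ncol(field)) & weak
}

# non-maximum suppression: keep a cell only if its magnitude is a local
# maximum along the (4-sector quantized) gradient direction
canny_nms <- function(mag, gx, gy) {
  nr <- nrow(mag); nc <- ncol(mag)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mag
  shift <- function(dx, dy) pad[2:(nr + 1) + dy, 2:(nc + 1) + dx]
  ang <- atan2(gy, gx)                       # gradient direction
  sector <- (round(ang / (pi / 4)) %% 4)     # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  n1 <- matrix(0, nr, nc); n2 <- n1
  for (s in 0:3) {
    dd <- switch(s + 1, c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
    idx <- sector == s
    a <- shift(dd[1], dd[2]); b <- shift(-dd[1], -dd[2])
    n1[idx] <- a[idx]; n2[idx] <- b[idx]
  }
  out <- mag
  out[!(mag >= n1 & mag >= n2)] <- 0
  out
}

bresenham_cells <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  n <- max(dx, dy) + 1L
  xs <- integer(n); ys <- integer(n)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    xs[i] <- x; ys[i] <- y
    if (x == x1 && y == y1) { xs <- xs[1:i]; ys <- ys[1:i]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  cbind(x = xs, y = ys)
}

#' Rasterize polylines onto the grid
#'
#' Marks every cell traversed by the 8-connected Bresenham walk along each
#' segment of each polyline. Vertices are given in cell units `(x, y)`;
#' fractional coordinates are rounded to the nearest cell. Cells falling
#' outside the grid are dropped (segments are clipped cell-wise).
#'
#' @param polylines list of numeric matrices with columns `(x, y)`; an empty
#'   list yields an all-`FALSE` mask.
#' @param grid a `grid_map` or integer `c(rows, cols)`.
#' @return logical matrix of marked cells.
#' @export
rasterize_polylines <- function(polylines, grid) {
  dm <- if (inherits(grid, "grid_map")) map_dims(grid) else as.integer(grid)
  out <- matrix(FALSE, dm[1], dm[2])
  for (pl in polylines) {
    pl <- as.matrix(pl)
    if (nrow(pl) == 0) next
    v <- round(pl)
    if (nrow(v) == 1) v <- rbind(v, v)
    for (i in seq_len(nrow(v) - 1)) {
      a <- v[i, ]; b <- v[i + 1, ]
      # canonical endpoint order makes the mask independent of traversal
      # direction (plain Bresenham is not reversal-symmetric)
      if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) { tmp <- a; a <- b; b <- tmp }
      cells <- bresenham_cells(a[1], a[2], b[1], b[2])
      ok <- cells[, 1] >= 1 & cells[, 1] <= dm[2] &
            cells[, 2] >= 1 & cells[, 2] <= dm[1]
      if (any(ok)) out[cbind(cells[ok, 2], cells[ok, 1])] <- TRUE
    }
  }
  out
}

#' Water-body masks: interiors and shorelines
#'
#' Cells whose centers fall inside a water polygon are split into shoreline
#' (inside cells with at least one 8-neighbor outside the polygon, or on the
#' grid edge) and interior (the rest). Interiors become inaccessible;
#' shorelines are linear features an agent may follow. The two outputs are
#' disjoint. A polygon covering a single cell yields one shoreline cell and
#' no interior.
#'
#' @param water_polygons list of simple polygon rings, each a numeric matrix
#'   with columns `(x, y)` in cell units (closed or open rings accepted).
#' @param grid a `grid_map` or integer `c(rows, cols)`.
#' @return list with logical matrices `inaccessible` and `shoreline`.
#' @export
build_water_layers <- function(water_polygons, grid) {
  dm <- if (inherits(grid, "grid_map")) map_dims(grid) else as.integer(grid)
  inside_all <- matrix(FALSE, dm[1], dm[2])
  for (poly in water_polygons) {
    poly <- as.matrix(poly)
    if (nrow(poly) < 3) next
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    xs <- max(1L, floor(xr[1])):min(dm[2], ceiling(xr[2]))
    ys <- max(1L, floor(yr[1])):min(dm[1], ceiling(yr[2]))
    if (length(xs) == 0 || length(ys) == 0) next
    gx <- rep(xs, times = length(ys))
    gy <- rep(ys, each = length(xs))
    ins <- pracma::inpolygon(gx, gy, poly[, 1], poly[, 2], boundary = TRUE)
    if (any(ins)) inside_all[cbind(gy[ins], gx[ins])] <- TRUE
  }
  if (!any(inside_all))
    return(list(inaccessible = inside_all, shoreline = inside_all))
  # shoreline: inside cells touching the outside (8-connectivity); cells on
  # the grid edge count as touching the outside
  nr <- dm[1]; nc <- dm[2]
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- inside_all
  all_nb_inside <- matrix(TRUE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    all_nb_inside <- all_nb_inside & pad[2:(nr + 1) + dy, 2:(nc + 1) + dx]
  }
  interior <- inside_all & all_nb_inside
  shoreline <- inside_all & !interior
  list(inaccessible = interior, shoreline = shoreline)
}
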