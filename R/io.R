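#' Read an elevation raster
#'
#' Reads a single-band elevation grid in meters, either from a plain
#' delimited-array file (whitespace- or comma-separated rows of numbers) or
#' from a TIFF (requires the `tiff` package; values are read as stored).
#' Geo-referencing is not parsed from the file: pass the map origin and cell
#' size to [assemble_map()] alongside the returned matrix.
#'
#' @param path file path; `.tif`/`.tiff` selects the TIFF reader.
#' @param sep field separator for delimited input (`""` = any whitespace).
#' @param as_is for TIFF input: set `TRUE` for integer-band DEMs so counts
#'   are returned unscaled; leave `FALSE` for float bands (stored values,
#'   the usual encoding for elevation in meters).
#' @return numeric matrix (rows x cols, row 1 = south edge).
#' @export
read_elevation <- function(path, sep = "", as_is = FALSE) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF elevation requires the 'tiff' package")
    img <- if (as_is) tiff::readTIFF(path, as.is = TRUE)
           else tiff::readTIFF(path)
    if (length(dim(img)) == 3) {
      if (dim(img)[3] != 1)
        stop("elevation TIFF must be single-band (got ", dim(img)[3],
             " channels)")
      img <- img[, , 1]
    }
    return(img)
  }
  m <- as.matrix(read.table(path, sep = sep, header = FALSE))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

# map-coordinate (x, y) matrix -> 1-based cell coordinates
coords_to_cells <- function(xy, origin = c(0, 0), cell_size = 1) {
  cbind(x = (xy[, 1] - origin[1]) / cell_size + 1,
        y = (xy[, 2] - origin[2]) / cell_size + 1)
}

geojson_geometries <- function(path) {
  g <- jsonlite::read_json(path)
  feats <- switch(g$type %||% "",
    FeatureCollection = lapply(g$features, `[[`, "geometry"),
    Feature = list(g$geometry),
    GeometryCollection = g$geometries,
    list(g))
  Filter(Negate(is.null), feats)
}

coord_matrix <- function(coords)
  do.call(rbind, lapply(coords, function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read vector features from GeoJSON
#'
#' `read_geojson_polylines()` extracts LineString and MultiLineString
#' geometries as a list of vertex matrices; `read_geojson_polygons()`
#' extracts the outer rings of Polygon and MultiPolygon geometries
#' (interior holes are ignored: a lake island finer than a cell is beyond
#' the grid resolution). Coordinates are converted from map units to
#' 1-based cell units through the affine transform `origin`/`cell_size`,
#' ready for [rasterize_polylines()] and [build_water_layers()].
#'
#' @param path GeoJSON file.
#' @param origin map coordinates of the cell (1, 1) center.
#' @param cell_size map units per cell.
#' @return list of numeric matrices with columns `(x, y)` in cell units.
#' @export
read_geojson_polylines <- function(path, origin = c(0, 0), cell_size = 1) {
  out <- list()
  for (geom in geojson_geometries(path)) {
    if (identical(geom$type, "LineString")) {
      out <- c(out, list(coord_matrix(geom$coordinates)))
    } else if (identical(geom$type, "MultiLineString")) {
      out <- c(out, lapply(geom$coordinates, coord_matrix))
    }
  }
  lapply(out, coords_to_cells, origin = origin, cell_size = cell_size)
}

#' @rdname read_geojson_polylines
#' @export
read_geojson_polygons <- function(path, origin = c(0, 0), cell_size = 1) {
  out <- list()
  for (geom in geojson_geometries(path)) {
    if (identical(geom$type, "Polygon")) {
      out <- c(out, list(coord_matrix(geom$coordinates[[1]])))
    } else if (identical(geom$type, "MultiPolygon")) {
      out <- c(out, lapply(geom$coordinates,
                           function(poly) coord_matrix(poly[[1]])))
    }
  }
  lapply(out, coords_to_cells, origin = origin, cell_size = cell_size)
}
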