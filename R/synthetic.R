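#' Configuration for the synthetic terrain generator
#'
#' Describes a test stand-in for real GIS layers: a smooth random elevation
#' surface (sum of Gaussian bumps over a flat base), a network of trail
#' polylines crossing the map, and rounded lake polygons whose interiors are
#' inaccessible and whose shorelines become linear features. Optionally the
#' ridge/drainage lines extracted from the synthetic relief (gradient +
#' Canny) are OR-ed into the feature layer, as they are for real elevation
#' data. The seed fixes the generated map bit-exactly.
#'
#' @param rows,cols grid dimensions.
#' @param cell_size meters per cell side.
#' @param n_bumps number of Gaussian elevation bumps.
#' @param bump_amplitude typical bump height (m).
#' @param bump_width typical bump standard deviation (cells).
#' @param n_trails number of trail polylines.
#' @param n_lakes number of lakes.
#' @param lake_radius typical lake radius (cells).
#' @param include_elevation_features also extract ridge/drainage lines from
#'   the synthetic relief.
#' @param seed integer seed.
#' @export
synthetic_map_config <- function(rows = 300, cols = 300,
                                 cell_size = 20000 / 3000,
                                 n_bumps = 12, bump_amplitude = 60,
                                 bump_width = 40,
                                 n_trails = 3, n_lakes = 1, lake_radius = 12,
                                 include_elevation_features = TRUE,
                                 seed = 1L) {
  stopifnot(rows >= 3, cols >= 3, cell_size > 0, n_bumps >= 0,
            n_trails >= 0, n_lakes >= 0, lake_radius >= 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cell_size = cell_size, n_bumps = as.integer(n_bumps),
                 bump_amplitude = bump_amplitude, bump_width = bump_width,
                 n_trails = as.integer(n_trails),
                 n_lakes = as.integer(n_lakes), lake_radius = lake_radius,
                 include_elevation_features = include_elevation_features,
                 seed = as.integer(seed)),
            class = "synthetic_map_config")
}

#' Generate a synthetic terrain grid
#'
#' Builds a reproducible `grid_map` from a [synthetic_map_config()]: relief,
#' trail network, lake interiors/shorelines, and (optionally) elevation
#' ridge lines, assembled with the layer-disjointness rule.
#'
#' @param config a [synthetic_map_config()].
#' @return a `grid_map`.
#' @export
generate_synthetic_map <- function(config = synthetic_map_config()) {
  stopifnot(inherits(config, "synthetic_map_config"))
  nr <- config$rows; nc <- config$cols
  if (config$n_lakes > 0 && 2.2 * config$lake_radius > min(nr, nc) / 2)
    stop("grid too small to host the requested lakes")
  with_seed(config$seed, {
    xs <- seq_len(nc); ys <- seq_len(nr)
    elev <- matrix(300, nr, nc)
    for (i in seq_len(config$n_bumps)) {
      cx <- runif(1, 1, nc); cy <- runif(1, 1, nr)
      amp <- config$bump_amplitude * runif(1, 0.3, 1)
      w <- config$bump_width * runif(1, 0.6, 1.4)
      elev <- elev + amp * exp(-outer((ys - cy)^2, (xs - cx)^2, "+") / (2 * w^2))
    }
    trails <- lapply(seq_len(config$n_trails), function(i) {
      horizontal <- runif(1) < 0.5
      n_wp <- 6
      if (horizontal) {
        x <- seq(1, nc, length.out = n_wp)
        y <- pmin(nr, pmax(1, runif(1, 0.2 * nr, 0.8 * nr) +
                             cumsum(rnorm(n_wp, 0, nr / 15))))
      } else {
        y <- seq(1, nr, length.out = n_wp)
        x <- pmin(nc, pmax(1, runif(1, 0.2 * nc, 0.8 * nc) +
                             cumsum(rnorm(n_wp, 0, nc / 15))))
      }
      cbind(x = x, y = y)
    })
    trail_mask <- rasterize_polylines(trails, c(nr, nc))
    lakes <- lapply(seq_len(config$n_lakes), function(i) {
      cx <- runif(1, 0.3 * nc, 0.7 * nc); cy <- runif(1, 0.3 * nr, 0.7 * nr)
      th <- seq(0, 2 * pi, length.out = 25)[-25]
      r <- config$lake_radius * (1 + 0.25 * sin(2 * th + runif(1, 0, 2 * pi)) +
                                   0.15 * sin(3 * th + runif(1, 0, 2 * pi)))
      cbind(x = cx + r * cos(th), y = cy + r * sin(th))
    })
    water <- build_water_layers(lakes, c(nr, nc))
    feature_masks <- list(trail_mask, water$shoreline)
    if (config$include_elevation_features) {
      gm <- gradient_magnitude(elev, sigma = 3)
      feature_masks <- c(feature_masks,
                         list(detect_elevation_linear_features(gm)))
    }
    m <- assemble_map(elev, feature_masks = feature_masks,
                      inaccessible_masks = list(water$inaccessible),
                      cell_size = config$cell_size)
    m$synthetic_config <- config
    m
  })
}
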