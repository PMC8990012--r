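#' Search incident record
#'
#' An incident pairs an initial planning point (IPP, the last known position
#' of the lost person) with the recorded find location, both as integer grid
#' cells, plus a subject-category tag.
#'
#' @param id incident identifier.
#' @param ipp integer `(x, y)` IPP cell.
#' @param find integer `(x, y)` find cell.
#' @param category subject category tag (default "hiker").
#' @param map_ref optional reference to the incident's map.
#' @return object of class `incident`.
#' @export
incident <- function(id, ipp, find, category = "hiker", map_ref = NA) {
  structure(list(id = id, ipp = as.integer(ipp), find = as.integer(find),
                 category = category, map_ref = map_ref),
            class = "incident")
}

#' Exclusion thresholds for incident screening
#'
#' Defaults follow the reference screening: drop incidents whose find
#' location is within 1 km of the IPP, outside the map, inside an
#' inaccessible area, or within 100 cells of the map boundary.
#'
#' @param min_distance_m minimum straight-line IPP-to-find distance (m).
#' @param boundary_margin_cells minimum Chebyshev distance of the find cell
#'   from the nearest grid edge.
#' @export
exclusion_config <- function(min_distance_m = 1000,
                             boundary_margin_cells = 100) {
  structure(list(min_distance_m = min_distance_m,
                 boundary_margin_cells = as.integer(boundary_margin_cells)),
            class = "exclusion_config")
}

#' Screen an incident against the exclusion criteria
#'
#' Applies the criteria in order and reports the first failure: find within
#' the minimum distance of the IPP (straight-line, meters), outside the map
#' limits, in an inaccessible cell, or within the boundary margin.
#'
#' @param incident an [incident()].
#' @param map a `grid_map`.
#' @param config an [exclusion_config()].
#' @return list with logical `keep` and a `reason` string ("ok" when kept).
#' @export
apply_exclusion_criteria <- function(incident, map,
                                     config = exclusion_config()) {
  dm <- map_dims(map)
  f <- incident$find
  d <- sqrt(sum((incident$ipp - f)^2)) * map$cell_size
  if (d < config$min_distance_m)
    return(list(keep = FALSE, reason = sprintf(
      "find location within %.3g km of the IPP", config$min_distance_m / 1000)))
  if (f[1] < 1 || f[1] > dm[2] || f[2] < 1 || f[2] > dm[1])
    return(list(keep = FALSE, reason = "find location outside the map limits"))
  if (map$inaccessible[f[2], f[1]])
    return(list(keep = FALSE, reason = "find location in an inaccessible area"))
  edge <- min(f[1] - 1, dm[2] - f[1], f[2] - 1, dm[1] - f[2])
  if (edge < config$boundary_margin_cells)
    return(list(keep = FALSE, reason = sprintf(
      "find location within %d cells of the map boundary",
      config$boundary_margin_cells)))
  list(keep = TRUE, reason = "ok")
}

#' Read and write incident tables
#'
#' The cell dialect is a CSV with columns `id, ipp_x, ipp_y, find_x, find_y`
#' (cell units) and optionally `category`. The lon/lat dialect has columns
#' `id, ipp_lon, ipp_lat, find_lon, find_lat` and requires `transform`, an
#' affine geo-transform `list(origin = c(lon0, lat0), deg_per_cell =
#' c(dlon, dlat))` mapping coordinates to cells by
#' `cell = round((coord - origin) / deg_per_cell) + 1`.
#'
#' @param path CSV file path.
#' @param transform optional affine transform for lon/lat input.
#' @return `read_incidents()` returns a list of [incident()] objects;
#'   `write_incidents()` writes the cell dialect and returns `path`
#'   invisibly.
#' @export
read_incidents <- function(path, transform = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cell_cols <- c("ipp_x", "ipp_y", "find_x", "find_y")
  ll_cols <- c("ipp_lon", "ipp_lat", "find_lon", "find_lat")
  if (!("id" %in% names(df))) stop("incident file is missing column: id")
  if (all(cell_cols %in% names(df))) {
    cols <- cell_cols
    to_cell <- function(v, axis) v
  } else if (all(ll_cols %in% names(df))) {
    if (is.null(transform))
      stop("lon/lat incident file requires a geo-transform")
    cols <- ll_cols
    to_cell <- function(v, axis)
      round((v - transform$origin[axis]) / transform$deg_per_cell[axis]) + 1
  } else {
    missing <- setdiff(cell_cols, names(df))
    stop("incident file is missing columns: ", paste(missing, collapse = ", "))
  }
  for (cc in cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) | is.na(df[[cc]]))
    if (length(bad) > 0)
      stop("non-numeric coordinate '", cc, "' in row ",
           paste(bad + 1, collapse = ", "), " of ", path)
    df[[cc]] <- v
  }
  lapply(seq_len(nrow(df)), function(i) {
    incident(id = df$id[i],
             ipp = c(to_cell(df[[cols[1]]][i], 1), to_cell(df[[cols[2]]][i], 2)),
             find = c(to_cell(df[[cols[3]]][i], 1), to_cell(df[[cols[4]]][i], 2)),
             category = if ("category" %in% names(df)) df$category[i] else "hiker")
  })
}

#' @param incidents list of [incident()] objects.
#' @rdname read_incidents
#' @export
write_incidents <- function(incidents, path) {
  df <- do.call(rbind, lapply(incidents, function(inc)
    data.frame(id = inc$id, ipp_x = inc$ipp[1], ipp_y = inc$ipp[2],
               find_x = inc$find[1], find_y = inc$find[2],
               category = inc$category)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic incident from a known behavioral profile
#'
#' Simulates one trajectory from the map center under the ground-truth
#' profile, samples the find location at a time drawn uniformly within the
#' mobile window (search-incident records carry no timing, so any time in
#' the window is equally plausible), and redraws (bounded retries) until the
#' incident passes the exclusion screen. Used for end-to-end
#' parameter-recovery testing.
#'
#' @param map a `grid_map`.
#' @param truth_pmf the generating [behavior_pmf()].
#' @param mobile_hours width of the mobile window (<= `config$hours`).
#' @param config a [sim_config()].
#' @param seed integer seed for this incident.
#' @param exclusion an [exclusion_config()].
#' @param max_retries retry budget before giving up.
#' @param id incident identifier.
#' @return list with the accepted `incident` and its ground `truth`
#'   (generating pmf, trajectory seed, sampled time index).
#' @export
generate_synthetic_incident <- function(map, truth_pmf, mobile_hours,
                                        config = sim_config(), seed = 1L,
                                        exclusion = exclusion_config(),
                                        max_retries = 100L, id = "syn-1") {
  truth_pmf <- behavior_pmf(truth_pmf)
  if (mobile_hours > config$hours)
    stop("mobile_hours cannot exceed the simulated hours")
  mobile_steps <- max(1L, round(mobile_hours * config$steps_per_hour))
  draws <- with_seed(seed, list(
    traj_seeds = sample.int(2147483646L, max_retries),
    t_idx = sample.int(mobile_steps, max_retries, replace = TRUE) + 1L))
  center <- map_center(map)
  last_reason <- "no attempt made"
  for (a in seq_len(max_retries)) {
    traj <- simulate_lp(center, truth_pmf, map, config,
                        seed = draws$traj_seeds[a])
    find <- traj$cells[draws$t_idx[a], ]
    inc <- incident(id = id, ipp = center, find = find,
                    category = "synthetic")
    chk <- apply_exclusion_criteria(inc, map, exclusion)
    if (chk$keep) {
      truth <- list(pmf = truth_pmf, seed = draws$traj_seeds[a],
                    time_index = draws$t_idx[a])
      return(list(incident = inc, truth = truth))
    }
    last_reason <- chk$reason
  }
  stop("could not generate an includable incident in ", max_retries,
       " attempts (last exclusion: ", last_reason, "); the ground-truth ",
       "profile may be too sedentary for the exclusion thresholds")
}
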