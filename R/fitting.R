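#' Closest point of a trajectory to the find location
#'
#' Finds the trajectory cell minimizing Euclidean distance to the find
#' location; ties are resolved to the earliest time index. Distances are
#' reported in meters (cell distance times `cell_size`).
#'
#' @param trajectory an `lp_trajectory` or an integer cell matrix `(x, y)`.
#' @param find integer `(x, y)` find cell.
#' @param cell_size meters per cell; defaults to the trajectory's own.
#' @return list with `cell`, `time_index` (1-based position index),
#'   `time_hours` (when steps-per-hour is known) and `distance_m`.
#' @export
closest_point <- function(trajectory, find, cell_size = NULL) {
  if (inherits(trajectory, "lp_trajectory")) {
    cells <- trajectory$cells
    if (is.null(cell_size)) cell_size <- trajectory$cell_size
    sph <- trajectory$steps_per_hour
  } else {
    cells <- as.matrix(trajectory)
    if (is.null(cell_size)) cell_size <- 1
    sph <- NULL
  }
  if (nrow(cells) == 0) stop("empty trajectory")
  d2 <- (cells[, 1] - find[1])^2 + (cells[, 2] - find[2])^2
  i <- which.min(d2)                      # which.min takes the earliest tie
  list(cell = as.integer(cells[i, ]), time_index = i,
       time_hours = if (!is.null(sph)) (i - 1) / sph else NA_real_,
       distance_m = sqrt(d2[i]) * cell_size)
}

#' Two-sample energy distance
#'
#' The energy statistic `E(X, Y) = 2A - B - C` where A is the mean pairwise
#' distance between the X and Y samples and B, C are the mean pairwise
#' distances within X and within Y; the within-sample means are normalized
#' by n^2 (m^2), so zero self-distances are included. With a single Y
#' realization C is identically zero.
#'
#' @param X numeric matrix, one sample point per row.
#' @param Y numeric matrix, one sample point per row.
#' @return nonnegative energy distance in the units of the inputs.
#' @export
energy_distance <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- nrow(Y)
  if (n == 0) stop("X has no samples")
  if (m == 0) stop("Y has no samples")
  cross_mean <- function(P, Q) {
    # direct evaluation (no squared-norm expansion) keeps full precision;
    # loop over the smaller sample
    if (nrow(Q) > nrow(P)) { tmp <- P; P <- Q; Q <- tmp }
    tP <- t(P)
    s <- 0
    for (j in seq_len(nrow(Q)))
      s <- s + sum(sqrt(colSums((tP - Q[j, ])^2)))
    s / (nrow(P) * nrow(Q))
  }
  A <- cross_mean(X, Y)
  B <- 2 * sum(stats::dist(X)) / n^2
  C <- 2 * sum(stats::dist(Y)) / m^2
  2 * A - B - C
}

#' Energy statistic of replicate closest points against a find location
#'
#' Treats the closest points of the Monte Carlo replicates as realizations
#' of X and the single recorded find location as Y (n replicates, m = 1), in
#' meters, and evaluates [energy_distance()]. Lower is better; the statistic
#' vanishes exactly when every closest point coincides with the find.
#'
#' @param points numeric matrix of closest-point cells `(x, y)`, one row per
#'   replicate.
#' @param find `(x, y)` find cell.
#' @param cell_size meters per cell (1 leaves the statistic in cell units).
#' @return energy statistic in meters.
#' @export
energy_statistic <- function(points, find, cell_size = 1) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("no replicate closest points supplied")
  energy_distance(points * cell_size,
                  matrix(find * cell_size, nrow = 1))
}

#' Inverse energy-per-unit-distance weight
#'
#' The incident weight `w = (d / E)^L` with `d` the IPP-to-find distance and
#' `E` the incident's best energy statistic, both in meters, and `L` a
#' characteristic-length exponent (1/2 by default, emphasizing the better
#' fitting profiles). A perfect fit (`E = 0`) is capped at `max_weight` with
#' a warning.
#'
#' @param d IPP-to-find distance in meters (> 0).
#' @param E energy statistic in meters (>= 0).
#' @param L exponent.
#' @param max_weight cap applied when `E = 0`.
#' @return dimensionless weight.
#' @export
incident_weight <- function(d, E, L = 0.5, max_weight = 1e6) {
  if (d <= 0) stop("IPP-to-find distance must be positive")
  if (E < 0) stop("energy statistic cannot be negative")
  if (E == 0) {
    warning("zero energy statistic (perfect fit); weight capped at ",
            max_weight)
    return(max_weight)
  }
  min((d / E)^L, max_weight)
}

#' Best behavioral profile for one incident
#'
#' Simulates `config$replicates` trajectories from the incident's IPP for
#' every candidate profile, extracts each replicate's closest point to the
#' find location, scores the candidate with the energy statistic, and
#' selects the minimizer (ties broken by lexicographically smallest
#' profile). The same replicate seeds are reused across candidates (common
#' random numbers), so candidates are compared on identical noise.
#'
#' @param incident an [incident()].
#' @param lpts profile matrix from [enumerate_lpts()] (one PMF per row).
#' @param map a `grid_map`.
#' @param config a [sim_config()].
#' @return an `lp_fit`: the best `pmf`, its `energy` (m), the IPP-to-find
#'   `distance_m`, the `weight`, the full `energies` vector over candidates,
#'   and the best candidate's closest points and approach times.
#' @export
best_lpt_for_incident <- function(incident, lpts, map, config = sim_config()) {
  lpts <- as.matrix(lpts)
  n_lpt <- nrow(lpts)
  if (n_lpt == 0) stop("no candidate profiles supplied")
  energies <- numeric(n_lpt)
  cp_store <- vector("list", n_lpt)
  for (k in seq_len(n_lpt)) {
    reps <- simulate_replicates(incident$ipp, lpts[k, ], map, config)
    cps <- lapply(reps, closest_point, find = incident$find)
    pts <- do.call(rbind, lapply(cps, `[[`, "cell"))
    energies[k] <- energy_statistic(pts, incident$find, map$cell_size)
    cp_store[[k]] <- list(points = pts,
                          times_h = vapply(cps, `[[`, 0, "time_hours"))
  }
  best <- which(energies == min(energies))
  if (length(best) > 1) {
    ord <- do.call(order, as.data.frame(lpts[best, , drop = FALSE]))
    best <- best[ord[1]]
  }
  d <- sqrt(sum((incident$ipp - incident$find)^2)) * map$cell_size
  structure(list(
    incident_id = incident$id,
    pmf = behavior_pmf(lpts[best, ]),
    energy = energies[best],
    distance_m = d,
    weight = incident_weight(d, energies[best]),
    energies = energies,
    best_index = best,
    closest_points = cp_store[[best]]$points,
    closest_times_h = cp_store[[best]]$times_h),
    class = "lp_fit")
}

#' @export
print.lp_fit <- function(x, ...) {
  cat(sprintf("<lp_fit> incident %s: E = %.1f m, d = %.1f m, w = %.3f\n",
              as.character(x$incident_id), x$energy, x$distance_m, x$weight))
  print(x$pmf)
  invisible(x)
}

#' Weighted average behavioral profile
#'
#' Combines per-incident best profiles into one profile by the weighted sum
#' `(w_1 p_1 + ... + w_N p_N)` normalized by its component total (1-norm),
#' so the result is again a valid PMF. Invariant to rescaling all weights by
#' a positive constant.
#'
#' @param fits list of `lp_fit` objects, or a profile matrix (one PMF per
#'   row) when `weights` is given.
#' @param weights optional positive weights, one per profile.
#' @return a [behavior_pmf()].
#' @export
average_profile <- function(fits, weights = NULL) {
  if (is.null(weights)) {
    pmfs <- do.call(rbind, lapply(fits, function(f) unclass(f$pmf)))
    weights <- vapply(fits, `[[`, 0, "weight")
  } else {
    pmfs <- as.matrix(fits)
  }
  if (nrow(pmfs) == 0) stop("no fitted profiles supplied")
  if (any(!is.finite(weights) | weights < 0))
    stop("weights must be finite and nonnegative")
  num <- colSums(pmfs * weights)
  s <- sum(num)
  if (s <= 0) stop("all weights are zero; cannot form an average profile")
  behavior_pmf(num / s)
}
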