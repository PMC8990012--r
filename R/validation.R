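#' Percentile rank of an energy statistic
#'
#' The share (in percent) of reference energies that are greater than or
#' equal to `e`. Lower energies are better fits, so a high percentile means
#' the scored profile beats most of the reference candidates; the rank is
#' antitone in `e`.
#'
#' @param e energy statistic to rank.
#' @param reference numeric vector of reference energies (e.g. the full
#'   candidate-lattice energies of an incident).
#' @return percentile in `[0, 100]`.
#' @export
percentile_rank <- function(e, reference) {
  if (length(reference) == 0) stop("empty reference energies")
  100 * mean(reference >= e)
}

#' Leave-one-out cross-validation of the averaged profile
#'
#' For each incident i the averaged profile is re-trained on the other N - 1
#' fits, simulated for `config$replicates` Monte Carlo replicates from
#' incident i's IPP (a single profile instead of the full candidate
#' lattice), scored with the energy statistic, and ranked among incident i's
#' stored candidate-lattice energies.
#'
#' @param incidents list of [incident()] objects.
#' @param fits list of `lp_fit` objects aligned with `incidents`; each must
#'   carry its full `energies` table.
#' @param map a `grid_map`, or a function `(incident) -> grid_map`.
#' @param config a [sim_config()]; fold i uses seed `config$seed + i` so
#'   held-out simulations are independent across folds yet reproducible.
#' @return data frame with one row per fold: `incident_id`, `energy`,
#'   `percentile`, and the trained profile in columns `RW..BT`.
#' @export
loocv <- function(incidents, fits, map, config = sim_config()) {
  n <- length(incidents)
  if (n < 2) stop("LOOCV needs at least 2 incidents")
  if (length(fits) != n) stop("fits and incidents must align")
  for (f in fits)
    if (is.null(f$energies))
      stop("fit for incident ", f$incident_id,
           " is missing its candidate energy table")
  map_of <- if (is.function(map)) map else function(inc) map
  rows <- lapply(seq_len(n), function(i) {
    trained <- average_profile(fits[-i])
    m <- map_of(incidents[[i]])
    cfg <- config
    cfg$seed <- config$seed + i
    reps <- simulate_replicates(incidents[[i]]$ipp, trained, m, cfg)
    pts <- do.call(rbind, lapply(reps, function(tr)
      closest_point(tr, incidents[[i]]$find)$cell))
    e <- energy_statistic(pts, incidents[[i]]$find, m$cell_size)
    pct <- percentile_rank(e, fits[[i]]$energies)
    cbind(data.frame(incident_id = incidents[[i]]$id, energy = e,
                     percentile = pct),
          as.data.frame(as.list(unclass(trained))))
  })
  do.call(rbind, rows)
}

#' Effective-speed regression diagnostic
#'
#' Ordinary least squares of mean closest-approach time (hours) on
#' IPP-to-find distance (km), restricted to incidents closer than `cutoff_km`
#' (beyond which approach times saturate). The slope (hours per km) inverts
#' to an effective model speed in m/s: `speed = 1000 / (slope * 3600)`.
#'
#' @param mean_times_h mean closest-approach time per incident (hours).
#' @param distances_km IPP-to-find distance per incident (km).
#' @param cutoff_km distance cutoff; only `d < cutoff_km` points are fitted.
#' @return object of class `speed_fit`: `slope`, `intercept`, `r_squared`,
#'   `speed_mps` (NA with a warning when the slope is not positive),
#'   `cutoff_km`, `n`.
#' @export
effective_speed_fit <- function(mean_times_h, distances_km, cutoff_km = 4) {
  keep <- distances_km < cutoff_km
  if (sum(keep) < 2)
    stop("need at least 2 incidents below the distance cutoff")
  t <- mean_times_h[keep]; d <- distances_km[keep]
  fit <- lm(t ~ d)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  tss <- sum((t - mean(t))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(fit$residuals^2) / tss
  if (is.na(slope) || slope <= 0) {
    warning("non-positive slope; effective speed undefined")
    speed <- NA_real_
  } else {
    speed <- 1000 / (slope * 3600)
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 speed_mps = speed, cutoff_km = cutoff_km, n = sum(keep)),
            class = "speed_fit")
}

#' @export
print.speed_fit <- function(x, ...) {
  cat(sprintf("<speed_fit> t = %.3f d + %.3f (R^2 = %.4f, n = %d, d < %g km)\n",
              x$slope, x$intercept, x$r_squared, x$n, x$cutoff_km))
  cat(sprintf("  effective speed: %.3f m/s\n", x$speed_mps))
  invisible(x)
}
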