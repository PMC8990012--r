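#' Simulation configuration
#'
#' Bundles the discrete-time parameters: smoothing factor `alpha` in (0, 1]
#' (0.55 by default, chosen off the fair 0.5 weighting to avoid cancellation
#' between the position terms), simulated duration `hours` (K), `steps_per_hour`
#' (T, 850 for a 1.575 m/s walking speed on 6.67 m cells), Monte Carlo
#' `replicates` and the master `seed`.
#'
#' @param alpha smoothing factor in (0, 1]; `alpha = 1` disables memory.
#' @param hours simulated hours K.
#' @param steps_per_hour time steps per hour T.
#' @param replicates Monte Carlo replicate count.
#' @param seed integer master seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(alpha = 0.55, hours = 100, steps_per_hour = 850,
                       replicates = 500, seed = 1L) {
  stopifnot(alpha > 0, alpha <= 1, hours >= 1, steps_per_hour >= 1,
            replicates >= 1)
  structure(list(alpha = alpha, hours = as.integer(hours),
                 steps_per_hour = as.integer(steps_per_hour),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

n_steps_of <- function(config) config$hours * config$steps_per_hour

#' Initialize an agent at the initial planning point
#'
#' Places the agent at the IPP, draws the second position uniformly among
#' the accessible 8-neighborhood (using the current RNG stream) and sets the
#' initial heading from the implied velocity `v(1) = x(2) - x(1)`.
#'
#' @param ipp integer `(x, y)` cell; must be inside the map and accessible.
#' @param map a `grid_map`.
#' @return an `agent_state`: continuous positions `x_t`, `x_tm1`, rounded
#'   `cell`, `heading`, the position/behavior histories and the backtrack
#'   cursor.
#' @export
init_agent <- function(ipp, map) {
  ipp <- as.integer(ipp)
  dm <- map_dims(map)
  if (!(ipp[1] >= 1 && ipp[1] <= dm[2] && ipp[2] >= 1 && ipp[2] <= dm[1]))
    stop("initial position outside map")
  if (map$inaccessible[ipp[2], ipp[1]])
    stop("initial position is inaccessible")
  res <- cpp_init_agent(ipp, map$inaccessible)
  structure(list(
    x_t = as.numeric(res$x2), x_tm1 = as.numeric(ipp),
    cell = as.integer(res$x2), heading = res$heading,
    position_history = rbind(ipp, as.integer(res$x2), deparse.level = 0),
    behavior_history = c(NA_integer_, NA_integer_),
    backtrack_cursor = 1L, last_stayed = FALSE),
    class = "agent_state")
}

#' One-step-memory position smoothing
#'
#' The continuous position update
#' `x(t+1) = (2 - alpha) x(t) + (alpha - 1) x(t-1) + alpha v(t)` with
#' `v(t) = xhat(t+1) - x(t)`: the provisional strategy move `xhat` is blended
#' with the previous velocity so trajectories have walking-like smoothness.
#' With `alpha = 1` it returns `xhat` exactly.
#'
#' @param x_t,x_tm1 current and previous continuous positions (2-vectors).
#' @param x_hat provisional next cell from the strategy.
#' @param alpha smoothing factor in (0, 1].
#' @return continuous position `x(t+1)`.
#' @export
smooth_update <- function(x_t, x_tm1, x_hat, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  v <- x_hat - x_t
  (2 - alpha) * x_t + (alpha - 1) * x_tm1 + alpha * v
}

#' Advance the agent one time step
#'
#' Draws a strategy from the profile, computes its provisional cell, applies
#' the smoothing update, and enforces inaccessibility: if the rounded
#' smoothed cell is outside the map or inaccessible the agent stays put for
#' this step (positions and heading unchanged) while the histories still
#' record the step. Otherwise the heading is updated from the realized
#' displacement.
#'
#' @param state an `agent_state`.
#' @param pmf a [behavior_pmf()].
#' @param map a `grid_map`.
#' @param alpha smoothing factor.
#' @return the updated `agent_state`; `state$last_stayed` reports whether
#'   the inaccessibility rule fired.
#' @export
lp_step <- function(state, pmf, map, alpha = 0.55) {
  pmf <- behavior_pmf(pmf)
  beh <- state$behavior_history
  beh[is.na(beh)] <- -1L
  res <- cpp_step(state$x_t, state$x_tm1, as.integer(state$cell),
                  as.integer(state$heading),
                  as.integer(state$position_history[, 1]),
                  as.integer(state$position_history[, 2]),
                  as.integer(beh), as.integer(state$backtrack_cursor),
                  unclass(pmf), map$elevation, map$linear_features,
                  map$inaccessible, alpha)
  state$x_t <- res$x_t
  state$x_tm1 <- res$x_tm1
  state$cell <- res$cell
  state$heading <- res$heading
  state$backtrack_cursor <- res$cursor
  state$position_history <- rbind(state$position_history, res$cell,
                                  deparse.level = 0)
  state$behavior_history <- c(state$behavior_history, res$strategy)
  state$last_stayed <- res$stayed
  state
}

#' Simulate one trajectory
#'
#' Runs the agent for `hours * steps_per_hour` position updates (the random
#' initialization draw counts as the first), returning the rounded-cell path
#' of length `n_steps + 1` including the IPP. Fully deterministic given the
#' seed.
#'
#' @param ipp integer `(x, y)` starting cell.
#' @param pmf a [behavior_pmf()].
#' @param map a `grid_map`.
#' @param config a [sim_config()].
#' @param seed seed for this trajectory (defaults to `config$seed`).
#' @return an `lp_trajectory`: integer cell matrix `cells`, per-step strategy
#'   codes `behavior` (NA for the two initial positions), `stay_put_count`,
#'   `seed`, `cell_size`, `steps_per_hour`.
#' @export
simulate_lp <- function(ipp, pmf, map, config = sim_config(),
                        seed = config$seed) {
  pmf <- behavior_pmf(pmf)
  n_steps <- n_steps_of(config)
  res <- with_seed(seed,
    cpp_simulate(as.integer(ipp), unclass(pmf), map$elevation,
                 map$linear_features, map$inaccessible,
                 config$alpha, n_steps))
  beh <- rep(NA_character_, n_steps + 1)
  known <- !is.na(res$behavior)
  beh[known] <- lp_strategies()[res$behavior[known] + 1L]
  structure(list(cells = cbind(x = res$x, y = res$y), behavior = beh,
                 stay_put_count = res$stay_put_count, seed = seed,
                 cell_size = map$cell_size,
                 steps_per_hour = config$steps_per_hour),
            class = "lp_trajectory")
}

#' @export
print.lp_trajectory <- function(x, ...) {
  n <- nrow(x$cells)
  cat(sprintf("<lp_trajectory> %d positions (%.1f h at %d steps/h), seed %d\n",
              n, (n - 1) / x$steps_per_hour, x$steps_per_hour, x$seed))
  cat(sprintf("  start (%d, %d) -> end (%d, %d), stay-put steps: %d\n",
              x$cells[1, 1], x$cells[1, 2], x$cells[n, 1], x$cells[n, 2],
              x$stay_put_count))
  invisible(x)
}

child_seeds <- function(master, n) {
  with_seed(master, sample.int(2147483646L, n))
}

#' Simulate Monte Carlo replicates
#'
#' Runs `config$replicates` independent trajectories. Each replicate uses a
#' child seed derived deterministically from the master `config$seed`, so
#' the full replicate set is reproducible and order-stable.
#'
#' @inheritParams simulate_lp
#' @return list of `lp_trajectory` objects.
#' @export
simulate_replicates <- function(ipp, pmf, map, config = sim_config()) {
  seeds <- child_seeds(config$seed, config$replicates)
  lapply(seq_len(config$replicates), function(r)
    simulate_lp(ipp, pmf, map, config, seed = seeds[r]))
}
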