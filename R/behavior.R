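#' Behavioral profile (PMF over the six strategies)
#'
#' A lost-person type (LPT) is a probability mass function over the six
#' reorientation strategies, in the fixed order RW, RT, DT, SP, VE, BT. For
#' example `behavior_pmf(c(1/2, 0, 1/6, 1/3, 0, 0))` random-walks half the
#' time, direction-travels about 17% and stays put about 33% of steps.
#'
#' @param values numeric vector of six probabilities; must be nonnegative
#'   and sum to one within `1e-9`.
#' @return a named numeric vector of class `behavior_pmf`.
#' @export
behavior_pmf <- function(values) {
  values <- as.numeric(values)
  if (length(values) != 6)
    stop("a behavioral profile needs exactly 6 entries (got ",
         length(values), ")")
  if (any(!is.finite(values)))
    stop("behavioral profile entries must be finite")
  neg <- which(values < -1e-12)
  if (length(neg) > 0)
    stop("negative probability for strategy ",
         paste(lp_strategies()[neg], collapse = ", "))
  s <- sum(values)
  if (abs(s - 1) > 1e-9)
    stop(sprintf("probabilities must sum to 1 (got %.10g)", s))
  values[values < 0] <- 0
  structure(values, names = lp_strategies(), class = "behavior_pmf")
}

#' @export
print.behavior_pmf <- function(x, ...) {
  cat("<behavior_pmf> ",
      paste(sprintf("%s=%.3f", names(x), unclass(x)), collapse = " "), "\n")
  invisible(x)
}

#' Enumerate the lattice of behavioral profiles
#'
#' Lists every PMF whose entries are multiples of `step` and sum to one, in
#' ascending lexicographic order. With six strategies and `step = 1/6` this
#' is the standard lattice of `choose(11, 5) = 462` profiles.
#'
#' @param n_strategies number of strategies (columns).
#' @param step probability increment; `1/step` must be an integer.
#' @return numeric matrix with one profile per row and strategy-code column
#'   names (for `n_strategies = 6`).
#' @export
enumerate_lpts <- function(n_strategies = 6, step = 1/6) {
  stopifnot(n_strategies >= 1, step > 0)
  m <- 1 / step
  if (abs(m - round(m)) > 1e-9)
    stop("1/step must be an integer (got 1/step = ", m, ")")
  m <- as.integer(round(m))
  comp <- compositions_lex(m, n_strategies)
  out <- comp / m
  if (n_strategies == 6) colnames(out) <- lp_strategies()
  out
}

# all length-n integer vectors with nonnegative entries summing to m,
# ascending lexicographic order
compositions_lex <- function(m, n) {
  if (n == 1) return(matrix(m, 1, 1))
  blocks <- lapply(0:m, function(k) {
    sub <- compositions_lex(m - k, n - 1)
    cbind(rep(k, nrow(sub)), sub)
  })
  do.call(rbind, blocks)
}

#' Draw strategies from a behavioral profile
#'
#' Independent draws from the PMF by inverse-CDF on a uniform stream, so a
#' fixed seed reproduces the draw sequence exactly.
#'
#' @param pmf a [behavior_pmf()] (or 6-vector coercible to one).
#' @param n number of draws.
#' @return character vector of strategy codes.
#' @export
sample_strategy <- function(pmf, n = 1) {
  pmf <- behavior_pmf(pmf)
  u <- runif(n)
  idx <- findInterval(u, cumsum(unclass(pmf))) + 1L
  idx[idx > 6L] <- 6L
  lp_strategies()[idx]
}

#' Heading from a velocity vector
#'
#' Snaps a velocity to the nearest of the eight 45-degree compass sectors
#' (0 = E, 1 = NE, ..., 7 = SE, counter-clockwise). A zero velocity retains
#' the previous heading, so direction- and route-traveling keep a defined
#' "forward" after a stall.
#'
#' @param velocity numeric `(vx, vy)` in cells per step.
#' @param previous previous heading index in 0..7.
#' @return heading index in 0..7.
#' @export
body_frame_heading <- function(velocity, previous = 0L) {
  stopifnot(length(velocity) == 2, previous %in% 0:7)
  cpp_heading_from(velocity[1], velocity[2], as.integer(previous))
}

#' Provisional next cell for one strategy
#'
#' Computes the strategy's proposed cell on the 3 x 3 body-frame grid
#' centered at the agent and oriented by its heading:
#' \describe{
#'   \item{RW}{uniform over the 8 neighbors and the current cell.}
#'   \item{RT}{uniform over the (at most three) forward cells carrying a
#'     linear feature; with no feature ahead it behaves as RW.}
#'   \item{DT}{the single straight-ahead cell.}
#'   \item{SP}{the current cell.}
#'   \item{VE}{the highest-elevation cell among self and in-map neighbors;
#'     ties broken uniformly at random; at a local maximum the agent stays.}
#'   \item{BT}{the previous position; on consecutive BT draws a cursor walks
#'     one stored non-BT position further back through the history, clamped
#'     at the trajectory start.}
#' }
#' Accessibility is not checked here; the simulator enforces it.
#'
#' @param strategy strategy code ("RW", ...) or index 0..5.
#' @param state an `agent_state` (see [init_agent()]).
#' @param map a `grid_map`.
#' @return list with the proposed integer `cell` and the updated
#'   `backtrack_cursor`.
#' @export
propose_step <- function(strategy, state, map) {
  s <- strategy_index(strategy)
  beh <- state$behavior_history
  beh[is.na(beh)] <- -1L
  res <- cpp_propose(s, as.integer(state$cell), as.integer(state$heading),
                     as.integer(state$position_history[, 1]),
                     as.integer(state$position_history[, 2]),
                     as.integer(beh), as.integer(state$backtrack_cursor),
                     map$elevation, map$linear_features)
  list(cell = res$cell, backtrack_cursor = res$cursor)
}
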