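# shared in-code fixtures: tiny open maps and hand-built agent states

flat_map <- function(rows = 21, cols = 21, cell_size = 5,
                     elevation = 100, features = NULL, inaccessible = NULL) {
  elev <- matrix(elevation, rows, cols)
  assemble_map(elev,
               feature_masks = if (is.null(features)) list() else list(features),
               inaccessible_masks = if (is.null(inaccessible)) list()
                                    else list(inaccessible),
               cell_size = cell_size)
}

# minimal agent state at `cell` with a given heading; previous position one
# cell behind so the velocity is consistent with the heading when wanted
make_state <- function(cell, heading = 0L, prev = cell - c(1, 0),
                       behavior_history = c(NA_integer_, NA_integer_),
                       cursor = 1L) {
  structure(list(
    x_t = as.numeric(cell), x_tm1 = as.numeric(prev),
    cell = as.integer(cell), heading = as.integer(heading),
    position_history = rbind(as.integer(prev), as.integer(cell),
                             deparse.level = 0),
    behavior_history = behavior_history,
    backtrack_cursor = cursor, last_stayed = FALSE),
    class = "agent_state")
}

# independent ray-casting point-in-polygon oracle (even-odd rule)
pip_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > py) != (poly[j, 2] > py)) {
      xint <- poly[i, 1] + (py - poly[i, 2]) *
        (poly[j, 1] - poly[i, 1]) / (poly[j, 2] - poly[i, 2])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# brute-force double-loop energy statistic oracle (meters)
energy_oracle <- function(X, Y) {
  n <- nrow(X); m <- nrow(Y)
  A <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    A <- A + sqrt(sum((X[i, ] - Y[j, ])^2))
  A <- A / (n * m)
  B <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    B <- B + sqrt(sum((X[i, ] - X[j, ])^2))
  B <- B / n^2
  C <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    C <- C + sqrt(sum((Y[i, ] - Y[j, ])^2))
  C <- C / m^2
  2 * A - B - C
}

# order the marked cells of a rasterized segment along its major axis and
# return consecutive Chebyshev distances (1 everywhere iff 8-connected)
bresenham_oracle_walk <- function(mask, a, b) {
  cells <- which(mask, arr.ind = TRUE)     # (row = y, col = x)
  d <- b - a
  ord <- if (abs(d[1]) >= abs(d[2])) order(cells[, 2] * sign(d[1] + 0.5))
         else order(cells[, 1] * sign(d[2] + 0.5))
  cells <- cells[ord, , drop = FALSE]
  if (nrow(cells) < 2) return(1)
  pmax(abs(diff(cells[, 1])), abs(diff(cells[, 2])))
}

# brute-force lattice enumeration oracle via expand.grid
lpt_oracle <- function(n, m) {
  g <- as.matrix(expand.grid(rep(list(0:m), n)))
  g <- g[rowSums(g) == m, , drop = FALSE]
  g[do.call(order, as.data.frame(g)), , drop = FALSE] / m
}
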