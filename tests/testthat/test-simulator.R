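test_that("smoothing update reproduces hand-computed examples exactly", {
  expect_equal(smooth_update(c(10, 10), c(9, 10), c(11, 10), 0.55), c(11, 10))
  # staying put under momentum drifts forward: 1.45*11 - 0.45*10 = 11.45
  expect_equal(smooth_update(c(11, 10), c(10, 10), c(11, 10), 0.55),
               c(11.45, 10))
  # alpha = 1 removes all memory
  x <- c(3.2, 7.9)
  expect_equal(smooth_update(x, c(1, 1), c(4, 8), 1), c(4, 8))
})

test_that("per-step displacement respects the momentum bound", {
  set.seed(50)
  n <- 1e5
  alpha <- 0.55
  x_t <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  x_tm1 <- x_t + cbind(runif(n, -2, 2), runif(n, -2, 2))
  x_hat <- round(x_t) + cbind(sample(-1:1, n, TRUE), sample(-1:1, n, TRUE))
  x_new <- (2 - alpha) * x_t + (alpha - 1) * x_tm1 + alpha * (x_hat - x_t)
  step_len <- sqrt(rowSums((x_new - x_t)^2))
  prev_len <- sqrt(rowSums((x_t - x_tm1)^2))
  hat_len <- sqrt(rowSums((x_hat - x_t)^2))
  expect_true(all(step_len <= (1 - alpha) * prev_len + alpha * hat_len + 1e-9))
  # proposals within the rounded 3x3 neighborhood: hat_len <= sqrt(2) + 1/2,
  # so the displacement is bounded accordingly
  expect_true(all(step_len <= (1 - alpha) * prev_len +
                    alpha * (sqrt(2) + sqrt(2) / 2) + 1e-9))
})

test_that("initialization draws uniformly among accessible neighbors", {
  m <- flat_map()
  set.seed(60)
  cells <- t(replicate(8000, init_agent(c(10, 10), m)$cell))
  counts <- table(paste(cells[, 1], cells[, 2]))
  expect_equal(length(counts), 8)
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
  # with 3 inaccessible neighbors only 5 remain
  blk <- matrix(FALSE, 21, 21); blk[11, 9:11] <- TRUE   # N, NW, NE blocked
  mb <- flat_map(inaccessible = blk)
  set.seed(61)
  c2 <- t(replicate(5000, init_agent(c(10, 10), mb)$cell))
  expect_equal(length(table(paste(c2[, 1], c2[, 2]))), 5)
  expect_false(any(c2[, 2] == 11))
  # errors on invalid starts
  expect_error(init_agent(c(0, 5), m), "outside")
  blk2 <- matrix(FALSE, 21, 21); blk2[10, 10] <- TRUE
  expect_error(init_agent(c(10, 10), flat_map(inaccessible = blk2)),
               "inaccessible")
  set.seed(62); a <- init_agent(c(10, 10), m)
  set.seed(62); b <- init_agent(c(10, 10), m)
  expect_identical(a, b)
})

test_that("trajectories have the contracted length and are seed-deterministic", {
  m <- flat_map(rows = 100, cols = 100)
  cfg <- sim_config(hours = 2, steps_per_hour = 50, replicates = 2, seed = 9)
  tr <- simulate_lp(c(50, 50), c(1, 0, 0, 0, 0, 0), m, cfg)
  expect_equal(nrow(tr$cells), 2 * 50 + 1)
  expect_identical(tr$cells,
                   simulate_lp(c(50, 50), c(1, 0, 0, 0, 0, 0), m, cfg)$cells)
  expect_equal(sum(is.na(tr$behavior)), 2)
})

test_that("staying-put profiles stay confined near the start", {
  m <- flat_map(rows = 60, cols = 60)
  cfg <- sim_config(hours = 1, steps_per_hour = 850, replicates = 1, seed = 3)
  tr <- simulate_lp(c(30, 30), c(0, 0, 0, 1, 0, 0), m, cfg)
  cheb <- max(abs(tr$cells[, 1] - 30), abs(tr$cells[, 2] - 30))
  expect_lte(cheb, 3)
})

test_that("direction traveling converges to one cell per step after burn-in", {
  m <- flat_map(rows = 200, cols = 200)
  cfg <- sim_config(hours = 1, steps_per_hour = 120, replicates = 1, seed = 8)
  tr <- simulate_lp(c(100, 100), c(0, 0, 1, 0, 0, 0), m, cfg)
  late <- tr$cells[60:121, ]
  # ballistic regime: net displacement ~ 1 cell/step (sqrt(2) on diagonals)
  net <- sqrt(sum((late[nrow(late), ] - late[1, ])^2))
  expect_gte(net / (nrow(late) - 1), 0.9)
  expect_lte(max(pmax(abs(diff(late[, 1])), abs(diff(late[, 2])))), 2)
})

test_that("inaccessible areas are never entered and trigger stay-put", {
  # a wall of water right of the start
  blk <- matrix(FALSE, 41, 41); blk[, 22:24] <- TRUE
  m <- flat_map(rows = 41, cols = 41, inaccessible = blk)
  cfg <- sim_config(hours = 1, steps_per_hour = 850, replicates = 1, seed = 5)
  tr <- simulate_lp(c(20, 20), c(0, 0, 1, 0, 0, 0), m, cfg)  # DT pushes east
  expect_false(any(blk[cbind(tr$cells[, 2], tr$cells[, 1])]))
  expect_gt(tr$stay_put_count, 0)
  # mixed profile on a lake map never enters the interior either
  ms <- generate_synthetic_map(synthetic_map_config(rows = 80, cols = 80,
                                                    lake_radius = 8, seed = 6))
  tr2 <- simulate_lp(map_center(ms), rep(1/6, 6), ms,
                     sim_config(hours = 1, steps_per_hour = 850,
                                replicates = 1, seed = 13))
  expect_false(any(ms$inaccessible[cbind(tr2$cells[, 2], tr2$cells[, 1])]))
})

test_that("consecutive cells stay within Chebyshev distance 2 for BT-free profiles", {
  m <- generate_synthetic_map(synthetic_map_config(rows = 100, cols = 100,
                                                   seed = 7))
  cfg <- sim_config(hours = 1, steps_per_hour = 850, replicates = 1, seed = 21)
  for (pmf in list(c(1, 0, 0, 0, 0, 0), c(0.2, 0.3, 0.3, 0.1, 0.1, 0))) {
    tr <- simulate_lp(map_center(m), pmf, m, cfg)
    jumps <- pmax(abs(diff(tr$cells[, 1])), abs(diff(tr$cells[, 2])))
    expect_lte(max(jumps), 2)
  }
})

test_that("pure random walking with alpha = 1 diffuses like a lazy 9-cell walk", {
  m <- flat_map(rows = 401, cols = 401)
  cfg <- sim_config(alpha = 1, hours = 1, steps_per_hour = 400,
                    replicates = 150, seed = 77)
  reps <- simulate_replicates(c(201, 201), c(1, 0, 0, 0, 0, 0), m, cfg)
  # E[|x(t)-x(0)|^2] = t * E[step^2] with E[step^2] = 2 * (6/9) = 4/3
  sq <- sapply(reps, function(tr) sum((tr$cells[401, ] - tr$cells[1, ])^2))
  se <- sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - 400 * 4/3), 3 * se)
})

test_that("replicates use deterministic child seeds and are order-stable", {
  m <- flat_map(rows = 60, cols = 60)
  cfg <- sim_config(hours = 1, steps_per_hour = 60, replicates = 4, seed = 42)
  r1 <- simulate_replicates(c(30, 30), rep(1/6, 6), m, cfg)
  r2 <- simulate_replicates(c(30, 30), rep(1/6, 6), m, cfg)
  expect_equal(length(r1), 4)
  for (i in 1:4) expect_identical(r1[[i]]$cells, r2[[i]]$cells)
  # a single replicate equals simulate_lp under the first child seed
  cfg1 <- cfg; cfg1$replicates <- 1L
  single <- simulate_replicates(c(30, 30), rep(1/6, 6), m, cfg1)[[1]]
  seed1 <- withr::with_seed(42, sample.int(2147483646L, 1))
  expect_identical(single$cells,
                   simulate_lp(c(30, 30), rep(1/6, 6), m, cfg1, seed = seed1)$cells)
})

test_that("stepwise API and the trajectory loop are the same dynamics", {
  m <- generate_synthetic_map(synthetic_map_config(rows = 60, cols = 60,
                                                   n_lakes = 0, seed = 9))
  pmf <- behavior_pmf(c(0.2, 0.2, 0.2, 0.1, 0.1, 0.2))
  cfg <- sim_config(hours = 1, steps_per_hour = 150, replicates = 1)
  tr <- simulate_lp(map_center(m), pmf, m, cfg, seed = 31)
  set.seed(31)
  st <- init_agent(map_center(m), m)
  for (i in seq_len(150 - 1)) st <- lp_step(st, pmf, m, cfg$alpha)
  expect_identical(unname(st$position_history), unname(tr$cells))
})
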