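test_that("behavioral profile validation", {
  p <- behavior_pmf(c(1/2, 0, 1/6, 1/3, 0, 0))
  expect_s3_class(p, "behavior_pmf")
  expect_equal(unname(p[c("RW", "DT", "SP")]), c(1/2, 1/6, 1/3))
  expect_s3_class(behavior_pmf(c(1, 0, 0, 0, 0, 0)), "behavior_pmf")
  expect_error(behavior_pmf(c(0.5, 0.5, 0.5, 0, 0, 0)), "sum to 1")
  expect_error(behavior_pmf(c(-0.1, 0.6, 0.5, 0, 0, 0)), "negative.*RW")
  expect_error(behavior_pmf(c(1, 0, 0, 0, 0)), "6 entries")
})

test_that("lattice enumeration matches the brute-force oracle", {
  expect_equal(nrow(enumerate_lpts(6, 1/6)), 462)
  expect_equal(enumerate_lpts(2, 1/2), rbind(c(0, 1), c(1/2, 1/2), c(1, 0)),
               ignore_attr = TRUE)
  one_hot <- enumerate_lpts(6, 1)
  expect_equal(nrow(one_hot), 6)
  expect_true(all(rowSums(one_hot == 1) == 1))
  for (n in 2:4) for (m in 1:6) {
    got <- enumerate_lpts(n, 1 / m)
    expect_equal(nrow(got), choose(m + n - 1, n - 1))
    expect_equal(unname(got), unname(lpt_oracle(n, m)),
                 label = sprintf("lattice n=%d m=%d", n, m))
  }
  expect_error(enumerate_lpts(3, 0.3), "integer")
})

test_that("every lattice profile is a valid PMF", {
  lpts <- enumerate_lpts(6, 1/6)
  expect_true(all(abs(rowSums(lpts) - 1) < 1e-12))
  expect_true(all(lpts >= 0))
  expect_equal(nrow(unique(lpts)), nrow(lpts))
})

test_that("strategy sampling is reproducible and matches the PMF", {
  p <- behavior_pmf(c(1/2, 0, 1/6, 1/3, 0, 0))
  set.seed(10); a <- sample_strategy(p, 1000)
  set.seed(10); b <- sample_strategy(p, 1000)
  expect_identical(a, b)
  expect_true(all(sample_strategy(behavior_pmf(c(0, 0, 0, 1, 0, 0)), 200) == "SP"))
  expect_false(any(a %in% c("RT", "VE", "BT")))
  # 60k draws within 3 binomial standard errors componentwise
  set.seed(11); big <- sample_strategy(p, 60000)
  for (s in c("RW", "DT", "SP")) {
    prob <- unname(p[s])
    se <- sqrt(prob * (1 - prob) / 60000)
    expect_lt(abs(mean(big == s) - prob), 3 * se)
  }
})

test_that("headings snap velocities to the nearest 45-degree sector", {
  expect_equal(body_frame_heading(c(1, 0)), 0)                 # E
  expect_equal(body_frame_heading(c(3, -1)), 0)                # -18.4 deg -> E
  expect_equal(body_frame_heading(c(0, 0), previous = 2), 2)   # stall keeps N
  expect_equal(body_frame_heading(c(1, 1)), 1)                 # NE
  expect_equal(body_frame_heading(c(-2, 0.1)), 4)              # W
  expect_equal(body_frame_heading(c(0.2, -1)), 6)              # S-ish
})

test_that("strategy proposals follow the body-frame update rules", {
  m <- flat_map()
  st <- make_state(c(10, 10), heading = 0)          # facing east
  expect_equal(propose_step("SP", st, m)$cell, c(10, 10))
  expect_equal(propose_step("DT", st, m)$cell, c(11, 10))
  # VE: NE neighbor 5 m higher wins; at a strict local max the agent stays
  elev <- matrix(100, 21, 21); elev[11, 11] <- 105
  mv <- assemble_map(elev, cell_size = 5)
  expect_equal(propose_step("VE", st, mv)$cell, c(11, 11))
  elev2 <- matrix(100, 21, 21); elev2[10, 10] <- 110
  expect_equal(propose_step("VE", make_state(c(10, 10)),
                            assemble_map(elev2, cell_size = 5))$cell,
               c(10, 10))
  # first BT returns the previous position
  stb <- make_state(c(5, 5), prev = c(4, 5))
  expect_equal(propose_step("BT", stb, m)$cell, c(4, 5))
})

test_that("VE never proposes a lower-elevation cell", {
  set.seed(20)
  elev <- matrix(runif(625, 0, 50), 25, 25)
  m <- assemble_map(elev, cell_size = 5)
  for (i in 1:200) {
    cell <- c(sample(2:24, 1), sample(2:24, 1))
    got <- propose_step("VE", make_state(cell), m)$cell
    expect_gte(elev[got[2], got[1]], elev[cell[2], cell[1]])
  }
})

test_that("RT follows forward features and falls back to a random walk", {
  # features at front-left (NE) and front (E): split evenly between the two
  feat <- matrix(FALSE, 21, 21); feat[11, 11] <- TRUE; feat[10, 11] <- TRUE
  m <- flat_map(features = feat)
  st <- make_state(c(10, 10), heading = 0)
  set.seed(30)
  draws <- t(replicate(4000, propose_step("RT", st, m)$cell))
  tab <- table(paste(draws[, 1], draws[, 2]))
  expect_setequal(names(tab), c("11 10", "11 11"))
  expect_lt(abs(tab[["11 10"]] / 4000 - 0.5), 3 * sqrt(0.25 / 4000))
  # behind-the-agent features are ignored
  feat2 <- matrix(FALSE, 21, 21); feat2[10, 9] <- TRUE
  st2 <- make_state(c(10, 10), heading = 0)
  set.seed(31)
  d2 <- t(replicate(2000, propose_step("RT", st2, flat_map(features = feat2))$cell))
  expect_false(any(d2[, 1] == 9 & d2[, 2] == 10 &
                     !(d2[, 1] %in% 9:11 & d2[, 2] %in% 9:11)))
  # no features at all: uniform over the 9-cell neighborhood
  set.seed(32)
  d3 <- t(replicate(9000, propose_step("RT", st, flat_map())$cell))
  counts <- table(paste(d3[, 1], d3[, 2]))
  expect_equal(length(counts), 9)
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
})

test_that("RW proposals are uniform over the 9-cell neighborhood", {
  m <- flat_map()
  st <- make_state(c(10, 10))
  set.seed(33)
  d <- t(replicate(9000, propose_step("RW", st, m)$cell))
  counts <- table(paste(d[, 1], d[, 2]))
  expect_equal(length(counts), 9)
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
  expect_true(all(abs(d[, 1] - 10) <= 1 & abs(d[, 2] - 10) <= 1))
})

test_that("consecutive BT walks the cursor back through non-BT history", {
  m <- flat_map()
  # history: (2,2) (3,2) (4,2) (5,2) with behaviors NA NA RW RW
  st <- make_state(c(5, 2), prev = c(4, 2))
  st$position_history <- rbind(c(2L, 2L), c(3L, 2L), c(4L, 2L), c(5L, 2L))
  st$behavior_history <- c(NA_integer_, NA_integer_, 0L, 0L)
  first <- propose_step("BT", st, m)
  expect_equal(first$cell, c(4, 2))
  expect_equal(first$backtrack_cursor, 3)
  # pretend the BT step was taken; a second consecutive BT goes further back
  st$position_history <- rbind(st$position_history, c(4L, 2L))
  st$behavior_history <- c(st$behavior_history, 5L)
  st$backtrack_cursor <- first$backtrack_cursor
  st$cell <- c(4L, 2L)
  second <- propose_step("BT", st, m)
  expect_equal(second$cell, c(3, 2))
  # and clamps at the trajectory start
  st$backtrack_cursor <- 1L
  clamped <- propose_step("BT", st, m)
  expect_equal(clamped$cell, c(2, 2))
  expect_equal(clamped$backtrack_cursor, 1)
})

test_that("non-BT proposals stay within Chebyshev distance 1", {
  set.seed(40)
  m <- generate_synthetic_map(synthetic_map_config(rows = 40, cols = 40,
                                                   n_lakes = 0, seed = 3))
  for (i in 1:300) {
    cell <- c(sample(2:39, 1), sample(2:39, 1))
    s <- sample(c("RW", "RT", "DT", "SP", "VE"), 1)
    st <- make_state(cell, heading = sample(0:7, 1))
    got <- propose_step(s, st, m)$cell
    expect_lte(max(abs(got - cell)), 1)
  }
})
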