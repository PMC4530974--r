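test_that("a bright corridor is followed exactly", {
  g <- matrix(0, 5, 7); g[3, ] <- 1
  p <- shortest_path_boundary(g)
  expect_equal(p$rows, rep(3L, 7))
})

test_that("Dijkstra agrees with the exhaustive oracle on random small grids", {
  set.seed(101)
  for (i in 1:60) {
    M <- sample(2:6, 1); N <- sample(2:6, 1)
    g <- matrix(runif(M * N), M, N)
    a <- shortest_path_boundary(g)
    b <- brute_force_boundary(g)
    expect_equal(a$total_weight, b$total_weight, tolerance = 1e-12)
  }
})

test_that("the all-zero grid costs 2N + (N+1) w_min, verified by the oracle", {
  # straight row-1 path: N-1 real-real arcs at 2 + w_min and two
  # virtual-real arcs at 1 + w_min each
  w <- 1e-5
  for (N in c(2, 4, 6)) {
    g <- matrix(0, 4, N)
    expected <- 2 * N + (N + 1) * w
    expect_equal(shortest_path_boundary(g, w)$total_weight, expected,
                 tolerance = 1e-12)
    expect_equal(brute_force_boundary(g, w)$total_weight, expected,
                 tolerance = 1e-12)
  }
})

test_that("raising any gradient value never increases the optimal weight", {
  set.seed(102)
  for (i in 1:25) {
    g <- matrix(runif(30, 0, 0.8), 5, 6)
    w0 <- shortest_path_boundary(g)$total_weight
    j <- sample(length(g), 1)
    g[j] <- g[j] + 0.2
    expect_lte(shortest_path_boundary(g)$total_weight, w0 + 1e-12)
  }
})

test_that("a constant gradient shift lowers each real arc by 2c on a corridor", {
  # corridor path: N-1 real-real arcs (drop 2c each) + 2 virtual-real arcs
  # (drop c each) => total drops by 2 c N; the corridor itself is unchanged
  g <- matrix(0.1, 5, 6); g[2, ] <- 0.6
  cshift <- 0.25
  p0 <- shortest_path_boundary(g)
  p1 <- shortest_path_boundary(g + cshift)
  expect_equal(p1$rows, p0$rows)
  expect_equal(p0$total_weight - p1$total_weight, 2 * cshift * 6,
               tolerance = 1e-9)
})

test_that("equal-weight corridors yield the same total in both engines", {
  g <- matrix(0, 6, 5); g[2, ] <- 1; g[5, ] <- 1
  a <- shortest_path_boundary(g)
  b <- brute_force_boundary(g)
  expect_equal(a$total_weight, b$total_weight, tolerance = 1e-12)
  expect_true(all(a$rows %in% c(2L, 5L)))
})

test_that("1-column grid admits a single direct path", {
  p <- brute_force_boundary(matrix(0.5, 1, 3))
  expect_equal(p$rows, rep(1L, 3))
})

test_that("reported rows are in bounds and follow reachable ridges", {
  set.seed(103)
  for (i in 1:20) {
    g <- matrix(runif(8 * 12), 8, 12)
    p <- shortest_path_boundary(g)
    expect_true(all(p$rows >= 1 & p$rows <= 8))
  }
  # on a ridge whose row changes by at most 1 per column, the first-entry
  # rows trace the ridge and are 8-connected
  z <- c(3, 3, 4, 5, 5, 4, 3, 2, 2, 3)
  g <- matrix(0, 7, 10); g[cbind(z, 1:10)] <- 1
  p <- shortest_path_boundary(g)
  expect_equal(p$rows, as.integer(z))
  expect_true(all(abs(diff(p$rows)) <= 1))
})

test_that("graph search rejects invalid input", {
  expect_error(shortest_path_boundary(matrix(c(NA, 1, 1, 1), 2, 2)), "finite")
  expect_error(shortest_path_boundary(matrix(1, 2, 2), w_min = 0), "positive")
  expect_error(brute_force_boundary(matrix(0.5, 9, 4)), "refused")
})
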