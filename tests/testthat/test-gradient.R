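test_that("edge kernels have the matched-filter structure", {
  k <- edge_kernel("dark_to_bright")
  expect_equal(dim(k), c(11L, 5L))
  col <- c(1, 1, 1, 1, 1, 0, -1, -1, -1, -1, -1)
  for (j in 1:5) expect_equal(k[, j], col)
  expect_equal(colSums(k), rep(0, 5))
  expect_equal(edge_kernel("bright_to_dark"), -k)
})

test_that("fast separable gradient equals the naive convolution oracle", {
  set.seed(11)
  frame <- matrix(runif(20 * 14), 20, 14)
  for (orient in c("dark_to_bright", "bright_to_dark")) {
    fast <- compute_gradient(frame, orient)$values
    expect_equal(fast, naive_gradient(frame, orient), tolerance = 1e-12)
  }
})

test_that("a dark-to-bright step responds maximally on the transition band", {
  f <- step_frame(40, 12, edge = 20)
  g <- compute_gradient(f, "dark_to_bright")$values
  # sharp inter-pixel step: the two rows bracketing it share the peak
  expect_equal(max(g), 1)
  expect_true(all(g[c(19, 20), ] == 1))
  expect_true(all(g[-(15:25), ] < 1))
})

test_that("constant frames give all-zero gradients", {
  g <- compute_gradient(matrix(0.7, 15, 8), "dark_to_bright")$values
  expect_equal(g, matrix(0, 15, 8))
})

test_that("bright-to-dark of I equals dark-to-bright of 1 - I", {
  set.seed(12)
  frame <- matrix(runif(18 * 12), 18, 12)
  expect_equal(compute_gradient(frame, "bright_to_dark")$values,
               compute_gradient(1 - frame, "dark_to_bright")$values)
})

test_that("step response translates with the edge away from borders", {
  for (k in c(0, 3, 7)) {
    g <- compute_gradient(step_frame(60, 10, edge = 25 + k), "dark_to_bright")$values
    expect_equal(which(g[, 5] == 1), c(24, 25) + k)
  }
})

test_that("gradients stay in [0, 1] for any finite input", {
  set.seed(13)
  for (i in 1:10) {
    f <- matrix(runif(16 * 9, -2, 2), 16, 9)
    g <- compute_gradient(f, sample(c("dark_to_bright", "bright_to_dark"), 1))$values
    expect_gte(min(g), 0)
    expect_lte(max(g), 1)
  }
})

test_that("gradient rejects degenerate inputs", {
  expect_error(compute_gradient(matrix(1, 5, 5)), "kernel")
  expect_error(compute_gradient(matrix(c(NA, rep(1, 10 * 11 - 1)), 11, 10)),
               "finite")
})

test_that("per-column normalization rescales, zeroes constants, idempotent", {
  m <- cbind(c(0.2, 0.4, 0.6), c(0.5, 0.5, 0.5))
  n1 <- normalize_columns(m)
  expect_equal(n1[, 1], c(0, 0.5, 1))
  expect_equal(n1[, 2], c(0, 0, 0))
  expect_equal(normalize_columns(n1), n1)
  expect_error(normalize_columns(matrix(numeric(0), 0, 0)), "empty")
})
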