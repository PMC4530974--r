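test_that("identical surface sets give all-zero statistics", {
  s <- sets_from_diffs(rep(0, 20))
  st <- compare_surfaces(s$a, s$b)
  expect_equal(unlist(st$overall[c("mse", "sse", "mue", "e95")]),
               c(mse = 0, sse = 0, mue = 0, e95 = 0))
  expect_equal(st$overall$n, 20L)
})

test_that("alternating unit differences give MSE 0, MUE 1, SSE 1", {
  s <- sets_from_diffs(c(1, -1, 1, -1))
  st <- compare_surfaces(s$a, s$b)
  expect_equal(st$overall$mse, 0)
  expect_equal(st$overall$mue, 1)
  expect_equal(st$overall$sse, 1)       # population sd, n denominator
  expect_equal(st$overall$e95, 1)
})

test_that("E95 is the order statistic at ceiling(0.95 n)", {
  s <- sets_from_diffs(sample(1:100))
  st <- compare_surfaces(s$a, s$b)
  expect_equal(st$overall$e95, 95)
  s7 <- sets_from_diffs(c(3, 1, 7, 5, 2, 6, 4))   # n = 7 -> 7th order stat
  expect_equal(compare_surfaces(s7$a, s7$b)$overall$e95, 7)
})

test_that("swapping the arguments negates MSE and preserves the rest", {
  set.seed(31)
  s <- sets_from_diffs(rnorm(50))
  ab <- compare_surfaces(s$a, s$b)
  ba <- compare_surfaces(s$b, s$a)
  expect_equal(ba$overall$mse, -ab$overall$mse)
  expect_equal(ba$overall$sse, ab$overall$sse)
  expect_equal(ba$overall$mue, ab$overall$mue)
  expect_equal(ba$overall$e95, ab$overall$e95)
})

test_that("MUE dominates |MSE|, with equality under a single sign", {
  set.seed(32)
  for (i in 1:10) {
    s <- sets_from_diffs(rnorm(30))
    st <- compare_surfaces(s$a, s$b)
    expect_gte(st$overall$mue, abs(st$overall$mse) - 1e-12)
  }
  s1 <- sets_from_diffs(c(1, 2, 3))
  st1 <- compare_surfaces(s1$a, s1$b)
  expect_equal(st1$overall$mue, st1$overall$mse)
})

test_that("comparison aligns grids by their offsets", {
  a <- surface_set(list(ILM = matrix(1:12 + 0, 4, 3)), column_offset = 2,
                   check = FALSE)
  b <- surface_set(list(ILM = matrix(0, 6, 3)), column_offset = 0,
                   check = FALSE)
  st <- compare_surfaces(a, b)
  expect_equal(st$overall$n, 12L)       # columns 3..6 of b overlap all of a
  expect_equal(st$overall$mse, mean(1:12))
  c <- surface_set(list(ILM = matrix(0, 2, 3)), column_offset = 50,
                   check = FALSE)
  expect_error(compare_surfaces(a, c), "disjoint")
  d <- surface_set(list(`RPE-CH` = matrix(0, 4, 3)), check = FALSE)
  expect_error(compare_surfaces(a, d), "share no boundary")
})

test_that("per-boundary and pooled statistics are consistent", {
  base <- matrix(50, 10, 2)
  a <- surface_set(list(ILM = base + 1, `IS-OS` = base + 101), check = FALSE)
  b <- surface_set(list(ILM = base, `IS-OS` = base + 100), check = FALSE)
  st <- compare_surfaces(a, b)
  expect_equal(st$per_boundary$mue, c(1, 1))
  expect_equal(st$overall$mue, 1)
  expect_equal(sum(st$per_boundary$n), st$overall$n)
})
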