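test_that("flattening an already-flat reference changes nothing", {
  f <- matrix(runif(100), 10, 10)
  res <- flatten(f, rep(7, 10))
  expect_equal(res$record$shifts, rep(0L, 10))
  expect_equal(res$frame, f)
})

test_that("flatten/unflatten round-trips the frame away from fill rows", {
  set.seed(21)
  f <- matrix(runif(200), 20, 10)
  ref <- c(15, 14, 13, 12, 11, 11, 12, 13, 14, 15)
  res <- flatten(f, ref)
  back <- unflatten_frame(res$frame, res$record)
  for (x in 1:10) {
    s <- res$record$shifts[x]
    expect_equal(back[1:(20 - s), x], f[1:(20 - s), x])
  }
})

test_that("a tilted reference yields the arithmetic shift ladder", {
  f <- matrix(0, 12, 10)
  res <- flatten(f, 1:10)               # reference z = x
  expect_equal(res$record$target_row, 10)
  expect_equal(res$record$shifts, as.integer(9:0))
})

test_that("boundary flatten/unflatten round-trip is exact", {
  rec <- structure(list(shifts = c(3L, 1L, 0L, 2L), target_row = 10L),
                   class = "flatten_record")
  for (z in list(c(5, 6, 7, 8), c(5.25, 6.5, 7.75, 8.1), rep(9, 4))) {
    expect_equal(unflatten_boundary(flatten_boundary(z, rec), rec), z)
  }
  b <- oct_boundary(c(5, 6, 7, 8), 2, "ILM")
  expect_equal(unflatten_boundary(flatten_boundary(b, rec), rec)$z, b$z)
  expect_error(flatten_boundary(1:3, rec), "mismatch")
})

test_that("inter-frame regions follow the min/max +/- margin rule", {
  r <- interframe_region(seq(100, 120, length.out = 11), margin = 10,
                         frame_height = 496)
  expect_equal(c(r$z_top, r$z_bottom), c(90L, 130L))
  # clamped at the image top
  r2 <- interframe_region(rep(6, 5), margin = 10, frame_height = 50)
  expect_equal(c(r2$z_top, r2$z_bottom), c(1L, 16L))
  r3 <- interframe_region(c(40, 45), margin = 0, frame_height = 100)
  expect_equal(c(r3$z_top, r3$z_bottom), c(40L, 45L))
  # the region always contains the generating boundary
  set.seed(22)
  for (i in 1:10) {
    z <- runif(20, 30, 60)
    r <- interframe_region(z, margin = sample(0:10, 1), frame_height = 100)
    expect_true(all(z >= r$z_top & z <= r$z_bottom))
  }
})

test_that("intra-frame regions implement the three modes", {
  r <- intraframe_region(300, mode = "rect_below", height = 40,
                         frame_height = 496)
  expect_equal(c(r$z_top, r$z_bottom, r$M), c(300L, 339L, 40L))
  r2 <- intraframe_region(c(30, 50, 40), rep(300, 3),
                          mode = "rect_between_extremes")
  expect_equal(c(r2$z_top, r2$z_bottom), c(50L, 300L))
  r3 <- intraframe_region(rep(80, 4), rep(80, 4),
                          mode = "rect_between_extremes")
  expect_equal(r3$M, 1L)
  expect_error(intraframe_region(rep(100, 3), rep(50, 3),
                                 mode = "rect_between_extremes"), "inverted")
  rb <- intraframe_region(c(10, 12), c(20, 18), mode = "band")
  expect_equal(c(rb$z_top, rb$z_bottom), c(10L, 20L))
  g <- matrix(1, 25, 2)
  cr <- crop_region(g, rb)
  expect_equal(cr[1, 2], 0)    # row 10 is above column 2's band (starts 12)
  expect_equal(cr[11, 2], 0)   # row 20 is below column 2's band (ends 18)
  expect_equal(cr[1, 1], 1)    # row 10 opens column 1's band
  expect_equal(cr[11, 1], 1)   # row 20 closes column 1's band
})

test_that("the lower-bias map is the (z-1)/(M-1) ramp", {
  expect_equal(apply_lower_bias(matrix(1, 3, 1))[, 1], c(0, 0.5, 1))
  set.seed(23)
  m <- matrix(runif(40), 8, 5)
  expect_equal(apply_lower_bias(m)[8, ], m[8, ])        # bottom row unchanged
  expect_equal(apply_lower_bias(m)[1, ], rep(0, 5))
  b <- apply_lower_bias(matrix(1, 9, 3))
  expect_true(all(diff(b[, 1]) >= 0))                   # monotone in depth
  expect_error(apply_lower_bias(matrix(1, 1, 4)), "2 rows")
})

test_that("biasing makes the search select the lower of two equal edges", {
  g <- matrix(0, 10, 8)
  g[2, ] <- 0.8; g[8, ] <- 0.8
  plain <- shortest_path_boundary(g)
  expect_equal(plain$rows, rep(2L, 8))                  # tie broken upward
  biased <- shortest_path_boundary(apply_lower_bias(g))
  expect_equal(biased$rows, rep(8L, 8))                 # bias selects depth
})

test_that("masking zeroes the requested side and is idempotent", {
  m <- matrix(1, 10, 4)
  out <- mask_relative(m, rep(5, 4), "below")
  expect_equal(out[1:5, ], matrix(1, 5, 4))
  expect_equal(out[6:10, ], matrix(0, 5, 4))
  expect_equal(mask_relative(out, rep(5, 4), "below"), out)
  up <- mask_relative(m, rep(5, 4), "above")
  expect_equal(up[5:10, ], matrix(1, 6, 4))
  expect_equal(up[1:4, ], matrix(0, 4, 4))
  pair <- mask_relative(m, rep(6, 4), "outside_pair", b2 = rep(6, 4))
  expect_equal(colSums(pair), rep(1, 4))                # only the shared row
  expect_error(mask_relative(m, rep(12, 4), "below"), "outside")
})

test_that("masking below a detected edge forces the next path above it", {
  g <- matrix(0, 12, 6)
  g[9, ] <- 0.9                                         # strong deep edge
  g[4, ] <- 0.5                                         # weaker shallow edge
  first <- shortest_path_boundary(normalize_columns(apply_lower_bias(g)))
  expect_equal(first$rows, rep(9L, 6))
  masked <- mask_relative(g, first$rows, "below", pad = 1)
  second <- shortest_path_boundary(normalize_columns(masked))
  expect_equal(second$rows, rep(4L, 6))
  expect_true(all(second$rows < first$rows))
})

test_that("moving average truncates at the edges", {
  z <- c(1, 2, 3, 4, 5)
  expect_equal(moving_average(z, 1), z)
  expect_equal(moving_average(z, 3), c(1.5, 2, 3, 4, 4.5))
})

test_that("down-sampled search reduces to the plain search at factor 1", {
  set.seed(24)
  g <- matrix(runif(15 * 20), 15, 20)
  expect_equal(downsample_search_upsample(g, factor = 1, smooth_window = 1),
               as.numeric(shortest_path_boundary(g)$rows))
})

test_that("a flat bright row is recovered exactly at any factor", {
  g <- matrix(0, 12, 30); g[7, ] <- 1
  for (f in c(1, 2, 3))
    expect_equal(downsample_search_upsample(g, factor = f, smooth_window = 1),
                 rep(7, 30))
})

test_that("a gentle sinusoidal edge survives factor-2 down-sampling within 1 px", {
  W <- 120
  z <- round(15 + 3 * sin(2 * pi * seq_len(W) / 60))
  g <- matrix(0, 30, W)
  g[cbind(z, seq_len(W))] <- 1
  est <- downsample_search_upsample(g, factor = 2, smooth_window = 1)
  expect_lte(max(abs(est - z)), 1)
  # and stays within 1 px of the full-resolution path
  full <- downsample_search_upsample(g, factor = 1, smooth_window = 1)
  expect_lte(max(abs(est - full)), 1)
})
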