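test_that("phantom generation is deterministic in the seed", {
  sp <- small_flat_spec()
  sp$speckle_shape <- 20
  a <- generate_phantom(sp, seed = 7)
  b <- generate_phantom(sp, seed = 7)
  expect_identical(a$volume$frames, b$volume$frames)
  expect_identical(a$truth$surfaces, b$truth$surfaces)
  c <- generate_phantom(sp, seed = 8)
  expect_false(identical(a$volume$frames, c$volume$frames))
})

test_that("phantom generation does not disturb the global RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_phantom(small_flat_spec(), seed = 1))
  expect_equal(runif(3), before)
})

test_that("all named fixtures satisfy the geometric invariants", {
  for (nm in names(default_specs())) {
    sp <- phantom_fixture(nm)
    ps <- octrima3d:::phantom_surfaces(sp)
    expect_silent(octrima3d:::check_phantom_invariants(sp, ps$surfaces))
    labs <- boundary_labels()
    for (i in 1:7)
      expect_gte(min(ps$surfaces[[labs[i + 1]]] - ps$surfaces[[labs[i]]]), 2)
    if (sp$n_frames > 1) {
      for (lab in labs) {
        s <- ps$surfaces[[lab]]
        expect_lte(max(abs(s[, -1] - s[, -ncol(s)])), 10)
      }
    }
  }
})

test_that("generated truth passes the surface-set ordering validation", {
  ph <- generate_phantom(phantom_fixture("fovea_clean"))
  expect_silent(validate_surface_set(ph$truth))
  expect_equal(dim(ph$truth$surfaces[["ILM"]]), c(644L, 10L))
})

test_that("invariant-violating specs are refused with the constraint named", {
  sp <- small_flat_spec()
  sp$thickness_px["inl"] <- 1                 # thinner than the 2-px floor
  expect_error(generate_phantom(sp), "thinner than 2 px")
  sp2 <- small_flat_spec()
  sp2$ilm_depth_px <- 280                     # pushes RPE-CH out of the frame
  expect_error(generate_phantom(sp2), "axial extent")
  sp3 <- small_flat_spec(n_frames = 3L)
  sp3$frame_amp <- 12; sp3$frame_period <- 4  # adjacent-frame jump > 10 px
  expect_error(generate_phantom(sp3), "more than 10 px")
})

test_that("noiseless rendering is piecewise constant with blended transitions", {
  ph <- generate_phantom(small_flat_spec(n_frames = 1L))
  fr <- ph$volume$frames[[1]]
  z <- ph$truth$surfaces
  lv <- ph$spec$reflectivities
  x <- 10
  expect_equal(fr[z[["ILM"]][x, 1] - 1, x], unname(lv["vitreous"]))
  expect_equal(fr[z[["ILM"]][x, 1], x],
               unname((lv["vitreous"] + lv["rnfl"]) / 2))
  expect_equal(fr[z[["ILM"]][x, 1] + 1, x], unname(lv["rnfl"]))
  expect_equal(fr[z[["RPE-CH"]][x, 1] + 1, x], unname(lv["choroid"]))
})

test_that("vessel columns are attenuated below and brightened under the ILM", {
  sp <- small_flat_spec(n_frames = 1L)
  sp$vessels <- data.frame(center = 60, width = 9, attenuation = 0.35,
                           brightening = 1.3)
  ph <- generate_phantom(sp)
  fr <- ph$volume$frames[[1]]
  z1 <- ph$truth$surfaces[["ILM"]][60, 1]
  z6 <- ph$truth$surfaces[["IS-OS"]][60, 1]
  clean <- generate_phantom(small_flat_spec(n_frames = 1L))$volume$frames[[1]]
  expect_equal(fr[z1 + 5, 60], clean[z1 + 5, 60] * 1.3)
  expect_equal(fr[z6 + 2, 60], clean[z6 + 2, 60] * 0.35)
  expect_equal(fr[, 5], clean[, 5])           # far columns untouched
  expect_true(all(ph$vessel_mask[, 56:64]))
  expect_false(any(ph$vessel_mask[, c(50, 70)]))
})

test_that("unknown fixture names are rejected with the available list", {
  expect_error(phantom_fixture("nope"), "available")
})
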