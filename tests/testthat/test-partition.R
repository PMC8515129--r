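test_that("plane split partitions a cube symmetrically", {
  m <- cube_mask(10)                      # voxel centers at z = 0..9 mm
  parts <- split_by_plane(m, 4.5)
  expect_equal(mask_volume(parts$supra, "tumor"), 500)
  expect_equal(mask_volume(parts$intra, "tumor"), 500)
})

test_that("voxel centers exactly on the plane are intrasellar", {
  m <- cube_mask(10)
  parts <- split_by_plane(m, 4)           # slice z = 4 sits on the plane
  expect_equal(mask_volume(parts$intra, "tumor"), 500)
  expect_equal(mask_volume(parts$supra, "tumor"), 500)
})

test_that("plane above the whole tumor gives the V1 = 0 case", {
  m <- cube_mask(10)
  parts <- split_by_plane(m, 100)
  expect_equal(mask_volume(parts$supra, "tumor"), 0)
  expect_equal(mask_volume(parts$intra, "tumor"), 1000)
})

test_that("split errors on an empty tumor mask", {
  empty <- voxel_mask(array(0L, c(4, 4, 4)))
  expect_error(split_by_plane(empty, 1), "no tumor voxels")
})

test_that("volume is conserved and monotone in the plane position", {
  s <- sphere_mask(8, voxel = 1)
  total <- mask_volume(s, "tumor")
  v1_prev <- Inf
  for (z0 in c(-10, -4.2, -1, 0, 0.5, 3.7, 10)) {
    parts <- split_by_plane(s, z0)
    v1 <- mask_volume(parts$supra, "tumor")
    v2 <- mask_volume(parts$intra, "tumor")
    expect_identical(v1 + v2, total)      # exact in voxel arithmetic
    expect_lte(v1, v1_prev)               # raising z0 never increases V1
    v1_prev <- v1
  }
})

test_that("snowman split at the junction matches spherical-cap volumes", {
  ph <- make_phantom(phantom_spec("snowman", voxel = 0.5))
  parts <- split_by_plane(ph$mask, ph$truth$z0)
  expect_lt(abs(mask_volume(parts$supra, "tumor") - ph$truth$v1) /
              ph$truth$v1, 0.02)
  expect_lt(abs(mask_volume(parts$intra, "tumor") - ph$truth$v2) /
              ph$truth$v2, 0.02)
})

test_that("waist detection lands within one slice of the analytic junction", {
  spec <- phantom_spec("snowman", r_upper = 10, r_lower = 8,
                       center_distance = 15, voxel = 0.5)
  ph <- make_phantom(spec)
  z0_analytic <- (15^2 + 8^2 - 10^2) / (2 * 15)
  expect_lt(abs(detect_waist(ph$mask) - z0_analytic), 0.5 + 1e-9)
})

test_that("unimodal profiles raise the no-waist error", {
  el <- make_phantom(phantom_spec("ellipsoid", carotid_gap = 36))
  expect_error(detect_waist(el$mask), "no waist")
  expect_error(detect_waist(sphere_mask(6, voxel = 1)), "no waist")
})

test_that("a flat minimal plateau resolves to the lowest slice", {
  # slice areas 9,9,4,4,4,9,9: a 3-slice flat waist
  lab <- array(0L, c(5, 5, 7))
  for (k in c(1, 2, 6, 7)) lab[1:3, 1:3, k] <- 1L
  for (k in 3:5) lab[1:2, 1:2, k] <- 1L
  m <- voxel_mask(lab)                    # slice k at z = k - 1 mm
  expect_equal(detect_waist(m, smooth_window = 1), 2)
})

test_that("tumors spanning fewer than 3 slices are rejected", {
  lab <- array(0L, c(4, 4, 4))
  lab[, , 1:2] <- 1L
  expect_error(detect_waist(voxel_mask(lab)), "3 axial slices")
})
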