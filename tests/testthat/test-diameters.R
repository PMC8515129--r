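test_that("rectangle Feret diameter follows the center-to-center convention", {
  lab <- array(0L, c(20, 10, 1))
  lab[, , 1] <- 1L
  m <- voxel_mask(lab)
  res <- max_horizontal_diameter(m)
  expect_equal(res$d1, sqrt(19^2 + 9^2))
  expect_equal(res$reference_slice, 1L)
})

test_that("digitized sphere diameter is found at the equator", {
  s <- sphere_mask(15, voxel = 1)
  res <- max_horizontal_diameter(s)
  expect_lt(abs(res$d1 - 30), 1)                    # one in-plane voxel
  z_eq <- (dim(s$labels)[3] + 1) / 2                # grid centered at 0
  expect_lte(abs(res$reference_slice - z_eq), 1)
})

test_that("hull-accelerated Feret equals brute-force all-pairs search", {
  set.seed(42)
  for (rep in 1:8) {
    lab <- array(0L, c(15, 15, 3))
    for (k in 1:3) {
      n <- sample(2:40, 1)
      idx <- cbind(sample(15, n, TRUE), sample(15, n, TRUE), k)
      lab[idx] <- 1L
    }
    m <- voxel_mask(lab, spacing = c(0.7, 1.3, 2))
    oracle <- max(vapply(1:3, function(k) {
      idx <- which(m$labels[, , k] == 1L, arr.ind = TRUE)
      brute_force_feret(cbind((idx[, 1] - 1) * 0.7, (idx[, 2] - 1) * 1.3))
    }, numeric(1)))
    expect_equal(max_horizontal_diameter(m)$d1, oracle)
  }
})

test_that("single-voxel tumors yield 0 with a warning, not an error", {
  lab <- array(0L, c(5, 5, 5))
  lab[3, 3, 3] <- 1L
  expect_warning(res <- max_horizontal_diameter(voxel_mask(lab)),
                 "degenerate")
  expect_equal(res$d1, 0)
})

test_that("in-plane rotation before digitization barely moves D1", {
  base <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(15, 10, 8),
                                    carotid_gap = 40, voxel = 0.5))
  rot <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(15, 10, 8),
                                   carotid_gap = 40, voxel = 0.5,
                                   rotation_deg = 45))
  d0 <- max_horizontal_diameter(base$mask)$d1
  d45 <- max_horizontal_diameter(rot$mask)$d1
  expect_lt(abs(d45 - d0), 0.5)                     # < 1 in-plane voxel
  # a sphere is exactly rotation-invariant up to digitization
  s0 <- make_phantom(phantom_spec("snowman", r_upper = 9, r_lower = 9,
                                  center_distance = 10, voxel = 0.5))
  s45 <- make_phantom(phantom_spec("snowman", r_upper = 9, r_lower = 9,
                                   center_distance = 10, voxel = 0.5,
                                   rotation_deg = 45))
  expect_lt(abs(max_horizontal_diameter(s0$mask)$d1 -
                  max_horizontal_diameter(s45$mask)$d1), 0.5)
})

test_that("landmark distance reproduces simple geometry", {
  expect_equal(landmark_distance(c(-13, 0), c(13, 0)), 26)
  expect_equal(landmark_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_error(landmark_distance(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("tube-wall separation is recovered within one in-plane voxel", {
  ph <- make_phantom(phantom_spec("snowman", voxel = 0.5, carotid_gap = 24))
  # lower-sphere equator: slice at z = 0
  k <- round(1 - ph$mask$origin[3] / 0.5)   # slice whose center is z = 0
  d2 <- intercarotid_distance(ph$mask, k)
  expect_lt(abs(d2 - 24), 0.5 + 1e-9)
})

test_that("a missing carotid is reported by side", {
  lab <- array(0L, c(6, 6, 1))
  lab[1, 3, 1] <- 2L                      # left present only
  lab[3, 3, 1] <- 1L
  m <- voxel_mask(lab)
  expect_error(intercarotid_distance(m, 1), "right carotid not present")
  lab2 <- array(0L, c(6, 6, 1))
  lab2[6, 3, 1] <- 3L
  expect_error(intercarotid_distance(voxel_mask(lab2), 1),
               "left carotid not present")
})
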