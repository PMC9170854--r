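test_that("sphere, disk and peak masks match exhaustive lattice enumeration", {
  g <- grid_spec(c(25L, 25L, 25L), 4)  # odd grid: central voxel center at 0
  ctr <- c(0, 0, 0)
  roi10 <- sphere_roi("10mm", ctr, 10, g)
  roi13 <- sphere_roi("13mm", ctr, 13, g)
  expect_equal(nrow(sphere_mask_3d(roi10, g)$indices),
               enum_ball_count(ctr, 5, 4))        # 7 voxels
  expect_equal(nrow(sphere_mask_3d(roi10, g)$indices), 7)
  expect_equal(nrow(sphere_mask_3d(roi13, g)$indices),
               enum_ball_count(ctr, 6.5, 4))      # 19 voxels
  expect_equal(nrow(sphere_mask_3d(roi13, g)$indices), 19)
  expect_equal(nrow(disk_mask_2d(roi10, g)$indices), 5)
  pk <- peak_mask(c(13L, 13L, 13L), g)
  expect_equal(nrow(pk$indices),
               enum_ball_count(ctr, (3 * 1000 / (4 * pi))^(1 / 3), 4))
  expect_equal(nrow(pk$indices), 19)
})

test_that("degenerate voxel sizes give single-voxel masks", {
  g <- grid_spec(c(9L, 9L, 9L), 13)
  roi <- sphere_roi("tiny", c(0, 0, 0), 10, g)  # diameter < voxel pitch
  expect_equal(nrow(sphere_mask_3d(roi, g)$indices), 1)
  expect_equal(nrow(peak_mask(c(5L, 5L, 5L), g)$indices), 1)  # voxel > 12.5 mm
})

test_that("the peak mask respects the cubic lattice symmetries", {
  g <- grid_spec(c(25L, 25L, 25L), 4)
  pk <- peak_mask(c(13L, 13L, 13L), g)
  rel <- sweep(pk$indices, 2, c(13L, 13L, 13L))
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  # axis permutations and sign flips map the offset set onto itself
  expect_equal(key(rel[, c(2, 3, 1)]), key(rel))
  expect_equal(key(rel * matrix(c(-1, 1, -1), nrow(rel), 3, byrow = TRUE)),
               key(rel))
})

test_that("disk masks are subsets of sphere masks on the tie-broken plane", {
  g <- small_grid()  # 24 slices: z = 0 is equidistant from two slices
  roi <- sphere_roi("17mm", c(2, 2, 0), 17, g)
  zs <- g$origin_mm[3] + (seq_len(24) - 1) * g$voxel_size_mm
  lower <- max(which(zs <= 0))
  expect_equal(roi$central_plane_index, lower)  # lower slice on exact tie
  m3 <- sphere_mask_3d(roi, g)
  m2 <- disk_mask_2d(roi, g)
  key <- apply(m3$indices, 1, paste, collapse = ",")
  expect_true(all(apply(m2$indices, 1, paste, collapse = ",") %in% key))
  expect_true(all(m2$indices[, 3] == roi$central_plane_index))
})

test_that("masks at the grid edge error or warn as appropriate", {
  g <- grid_spec(c(8L, 8L, 8L), 4)
  roi <- sphere_roi("37mm", c(0, 0, 0), 37, g)  # grid only 32 mm wide
  expect_error(sphere_mask_3d(roi, g), "beyond the grid")
  g2 <- grid_spec(c(10L, 10L, 10L), 4)
  expect_warning(peak_mask(c(1L, 1L, 1L), g2), "clipped")
})

test_that("center-in mask volume converges to the true sphere volume", {
  g <- grid_spec(c(80L, 80L, 80L), 0.5)
  roi <- sphere_roi("37mm", c(0.123, 0.071, -0.05), 37, g)
  vol <- nrow(sphere_mask_3d(roi, g)$indices) * 0.5^3
  expect_equal(vol, 4 / 3 * pi * 18.5^3, tolerance = 0.02)
})

test_that("automatic detection recovers all six spheres on the truth image", {
  fx <- default_truth_cache()
  rois <- detect_spheres(fx$truth)
  expect_length(rois, 6)
  expect_equal(vapply(rois, function(r) r$nominal_diameter_mm, 0),
               c(10, 13, 17, 22, 28, 37))
  for (i in 1:6) {
    err <- sqrt(sum((rois[[i]]$center_mm - fx$geom$sphere_centers_mm[i, ])^2))
    expect_lt(err, fx$grid$voxel_size_mm)  # within one voxel
  }
})

test_that("geometry-mode detection is exact on the truth and robust to noise", {
  fx <- default_truth_cache()
  rois0 <- detect_spheres(fx$truth, geom_hint = fx$geom)
  for (i in 1:6)
    expect_equal(rois0[[i]]$center_mm, fx$geom$sphere_centers_mm[i, ],
                 tolerance = 0.5)
  # noisy frames at the default noise level: centers stay within one voxel
  nm <- noise_model()
  for (s in 1:20) {
    fr <- simulate_frame(fx$truth, 0, 30, nm, seed = 6000 + s)
    rois <- detect_spheres(fr, geom_hint = fx$geom)
    for (i in 1:6) {
      err <- sqrt(sum((rois[[i]]$center_mm - fx$geom$sphere_centers_mm[i, ])^2))
      expect_lt(err, fx$grid$voxel_size_mm)
    }
  }
})

test_that("detection fails informatively on a featureless image", {
  flat <- uniform_volume(7, n = 30L)
  expect_error(detect_spheres(flat), "no distinct hot regions")
})
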