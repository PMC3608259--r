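test_that("iso-surfaces of a signed-distance sphere sit at the right radius", {
  vol <- sphere_sdf_volume(8, 64, 1)
  m <- extract_isosurface(vol, 0)
  r <- sqrt(rowSums(m$vertices^2))
  expect_true(all(abs(r - 8) < 0.1))
  expect_true(mesh_is_closed(m))
  # level offset: tau = +1 is the sphere of radius 9
  m2 <- extract_isosurface(vol, 1)
  expect_equal(mean(sqrt(rowSums(m2$vertices^2))), 9, tolerance = 0.1)
  expect_true(max(abs(sqrt(rowSums(m2$vertices^2)) - 9)) < 0.5)
})

test_that("iso-levels outside the data range are rejected", {
  vol <- sphere_sdf_volume(8, 32, 2)
  expect_error(extract_isosurface(vol, max(vol$values) + 1), "range")
  expect_error(extract_isosurface(vol, min(vol$values)), "range")
})

test_that("threshold calibration finds the exact level on a distance volume", {
  vol <- sphere_sdf_volume(8, 40, 1.6)
  ref <- sphere_mesh(8, 48, 32)
  cal <- calibrate_threshold(vol, ref, seq(-2, 2, by = 1))
  expect_equal(cal$tau_star, 0)
  expect_equal(cal$objective_curve$tau[which.min(
    cal$objective_curve$mean_abs_distance)], cal$tau_star)
})

test_that("calibration is invariant to rigid motion of the reference", {
  set.seed(17)
  vol <- sphere_sdf_volume(8, 40, 1.6)
  ref <- sphere_mesh(8, 48, 32)
  tr <- random_rigid(max_angle = 20 * pi / 180, max_trans = 5)
  moved_ref <- transform_mesh(ref, tr$rotation, tr$translation)
  cal <- calibrate_threshold(vol, moved_ref, seq(-2, 2, by = 1))
  expect_lte(abs(cal$tau_star - 0), 1)  # at most one grid step
})

test_that("an inflated reference pulls the threshold below the half level", {
  model <- build_monoradicular(incisor_params_ref(), resolution = 40)
  vol <- blur_volume(voxelize_mesh(model$mesh, spacing = 0.5), sigma = 1)
  ref_inflated <- scale_mesh(model$mesh, 1 + 0.5 / 12,
                             center = colMeans(model$mesh$vertices))
  cal <- calibrate_threshold(vol, ref_inflated, seq(0.3, 0.7, by = 0.1))
  expect_lt(cal$tau_star, 0.5)
})

test_that("voxelisation volume matches the analytic solid", {
  sph <- sphere_mesh(6, 48, 32)
  vol <- voxelize_mesh(sph, spacing = 0.5)
  expect_equal(sum(vol$values) * 0.5^3, 4 / 3 * pi * 216,
               tolerance = 0.02 * 4 / 3 * pi * 216)
  expect_error(voxelize_mesh(cylinder_mesh(1, 1, 8, 3)), NA)
})
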