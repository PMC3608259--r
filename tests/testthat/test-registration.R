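test_that("rigid transforms compose, invert and validate", {
  set.seed(2)
  a <- random_rigid(); b <- random_rigid()
  p <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(apply_transform(compose_transforms(a, b), p),
               apply_transform(a, apply_transform(b, p)), tolerance = 1e-12)
  ident <- compose_transforms(a, invert_transform(a))
  expect_equal(rotation_angle(ident$rotation), 0, tolerance = 1e-9)
  expect_equal(ident$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
})

test_that("self-alignment returns the identity", {
  m <- build_monoradicular(incisor_params_ref(), resolution = 32)$mesh
  fit <- best_fit_align(m, m)
  expect_lt(rotation_angle(fit$transform$rotation), 1e-6)
  expect_lt(sqrt(sum(fit$transform$translation^2)), 1e-6)
  expect_lt(fit$rms, 1e-6)
})

test_that("a known rigid motion is recovered and rms never increases", {
  set.seed(31)
  fixed <- asymmetric_test_mesh(32L)
  tr <- random_rigid(max_angle = 15 * pi / 180, max_trans = 5)
  moving <- transform_mesh(fixed, tr$rotation, tr$translation)
  fit <- best_fit_align(moving, fixed)
  resid <- compose_transforms(fit$transform, tr)
  expect_lt(rotation_angle(resid$rotation), 1e-3)
  expect_lt(sqrt(sum(resid$translation^2)), 1e-3)
  expect_true(all(diff(fit$rms_history) <= 1e-9))
})

test_that("vertex noise sets the alignment floor", {
  set.seed(8)
  fixed <- asymmetric_test_mesh(40L)
  tr <- random_rigid(max_angle = 10 * pi / 180, max_trans = 3)
  moving <- transform_mesh(fixed, tr$rotation, tr$translation)
  moving$vertices <- moving$vertices +
    matrix(stats::rnorm(length(moving$vertices), 0, 0.05), ncol = 3)
  fit <- best_fit_align(moving, fixed)
  expect_lt(abs(fit$rms - 0.05), 0.02)
})

test_that("collinear geometry is rejected", {
  line <- triangle_mesh(cbind(seq_len(12), 0, 0),
                        matrix(c(1, 2, 3), 1, 3))
  sph <- sphere_mesh(3, 16, 12)
  expect_error(best_fit_align(line, sph), "collinear")
})

test_that("signed deviations follow the warm/cold convention", {
  s80 <- sphere_mesh(8, 64, 48)
  d0 <- signed_distance_map(s80, s80)
  expect_lt(max(abs(d0)), 1e-9)
  d_out <- signed_distance_map(sphere_mesh(8.5, 64, 48), s80)
  expect_equal(mean(d_out), 0.5, tolerance = 0.02)
  expect_true(all(abs(d_out - 0.5) < 0.05))
  d_in <- signed_distance_map(sphere_mesh(7.5, 64, 48), s80)
  expect_equal(mean(d_in), -0.5, tolerance = 0.02)
  expect_true(all(abs(d_in + 0.5) < 0.05))
  # open segmented surface: sign undefined
  open_tube <- cylinder_mesh(3, 10); open_tube$faces <- open_tube$faces[-1, ]
  expect_error(signed_distance_map(s80, open_tube), "closed")
})

test_that("dilating the parametric mesh increases the mean signed deviation", {
  seg <- build_monoradicular(incisor_params_ref(), resolution = 32)$mesh
  cen <- colMeans(seg$vertices)
  means <- vapply(c(0.98, 1.0, 1.02), function(s)
    mean(signed_distance_map(scale_mesh(seg, s, cen), seg)), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("deviation reports partition vertices and respect bounds", {
  seg <- build_monoradicular(incisor_params_ref(), resolution = 32)$mesh
  par_m <- scale_mesh(seg, 1.02, colMeans(seg$vertices))
  dmap <- signed_distance_map(par_m, seg)
  rep_ <- deviation_report(dmap, par_m)
  expect_equal(sum(rep_$n), nrow(par_m$vertices))
  expect_true(all(c("apex", "cej", "crown", "root") %in% rep_$region))
  ok <- rep_$n > 0
  expect_true(all(rep_$max_abs[ok] <= attr(rep_, "overall_max_abs") + 1e-12))
  expect_true(all(rep_$mean_abs[ok] >= 0))
  # constant field: every populated region mean equals the constant
  const <- structure(rep(0.5, nrow(par_m$vertices)), class = "distance_map")
  rep2 <- deviation_report(const, par_m)
  expect_true(all(abs(rep2$mean_abs[rep2$n > 0] - 0.5) < 1e-12))
  # all-zero map
  zero <- structure(rep(0, nrow(par_m$vertices)), class = "distance_map")
  rep3 <- deviation_report(zero, par_m)
  expect_true(all(rep3$max_abs[rep3$n > 0] == 0))
  # empty region reported with n = 0, no crash
  rep4 <- deviation_report(dmap, par_m, region_config = list(cej_z = 1e4))
  expect_true(any(rep4$n == 0))
})
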