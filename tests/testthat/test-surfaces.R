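test_that("lofting two circles gives a cylinder with the analytic area", {
  surf <- loft_sections(list(circle_section(3, 0), circle_section(3, 10)))
  m <- tessellate(surf, 64, 16)
  expect_lt(abs(mesh_area(m) - 2 * pi * 3 * 10) / (2 * pi * 3 * 10), 0.02)
  # open tube: not closed, two boundary loops
  expect_false(mesh_is_closed(m))
})

test_that("a near-point top section gives a cone-like loft with apex at the top", {
  surf <- loft_sections(list(circle_section(3, 0), circle_section(0.01, 10)))
  m <- tessellate(surf, 32, 12)
  expect_equal(max(m$vertices[, 3]), 10, tolerance = 1e-9)
})

test_that("lofts interpolate interior sections exactly", {
  surf <- loft_sections(list(circle_section(4, 0), circle_section(2, 5),
                             circle_section(1, 10)))
  m <- tessellate(surf, 64, 48)
  w5 <- toothrecon:::slice_widths(m, 5 + 1e-4)
  expect_equal(w5, 4.0, tolerance = 0.05)
})

test_that("loft rejects too few or open sections", {
  expect_error(loft_sections(list(circle_section(1, 0))), "at least 2")
  open_crv <- bspline_curve(matrix(stats::rnorm(12), 4, 3))
  expect_error(loft_sections(list(open_crv, open_crv)), "closed")
})

test_that("Coons patch reproduces a flat square and its boundaries", {
  e <- function(a, b) bspline_curve(rbind(a, b), degree = 1)
  patch <- coons_patch(list(e(c(0, 0, 0), c(1, 0, 0)),
                            e(c(1, 0, 0), c(1, 1, 0)),
                            e(c(1, 1, 0), c(0, 1, 0)),
                            e(c(0, 1, 0), c(0, 0, 0))))
  expect_equal(eval_surface(patch, 0.5, 0.5), matrix(c(0.5, 0.5, 0), 1),
               tolerance = 1e-12)
  # lift one edge to an arc: boundary reproduced exactly at its midpoint
  arc <- interpolate_bspline(rbind(c(0, 0, 0), c(0.5, 0, 1), c(1, 0, 0)))
  patch2 <- coons_patch(list(arc,
                             e(c(1, 0, 0), c(1, 1, 0)),
                             e(c(1, 1, 0), c(0, 1, 0)),
                             e(c(0, 1, 0), c(0, 0, 0))))
  expect_equal(eval_surface(patch2, 0.5, 0), evaluate_curve(arc, 0.5),
               tolerance = 1e-9)
})

test_that("Coons patch stays close to a quarter cylinder shell", {
  # boundaries of the quarter shell x^2+y^2=1, x,y >= 0, z in [0,2]
  th <- seq(0, pi / 2, length.out = 9)
  arc0 <- interpolate_bspline(cbind(cos(th), sin(th), 0))
  arc1 <- interpolate_bspline(cbind(rev(cos(th)), rev(sin(th)), 2))
  e <- function(a, b) bspline_curve(rbind(a, b), degree = 1)
  patch <- coons_patch(list(arc0, e(c(0, 1, 0), c(0, 1, 2)), arc1,
                            e(c(1, 0, 2), c(1, 0, 0))))
  g <- expand.grid(u = seq(0, 1, length.out = 40),
                   v = seq(0, 1, length.out = 15))
  p <- eval_surface(patch, g$u, g$v)
  dev <- abs(sqrt(p[, 1]^2 + p[, 2]^2) - 1)
  # regression number for the bilinear blend on this boundary set
  expect_lt(max(dev), 0.01)
})

test_that("an unclosed boundary loop is rejected", {
  e <- function(a, b) bspline_curve(rbind(a, b), degree = 1)
  expect_error(coons_patch(list(e(c(0, 0, 0), c(1, 0, 0)),
                                e(c(1, 0.5, 0), c(1, 1, 0)),
                                e(c(1, 1, 0), c(0, 1, 0)),
                                e(c(0, 1, 0), c(0, 0, 0)))),
               "not closed")
})

test_that("revolution surfaces match analytic areas", {
  prof <- bspline_curve(rbind(c(2, 0, 0), c(2, 0, 6)), degree = 1)
  m <- tessellate(revolve_profile(prof), 64, 8)
  expect_lt(abs(mesh_area(m) - 2 * pi * 2 * 6) / (2 * pi * 2 * 6), 0.02)
  sph <- sphere_mesh(5, 64, 48)
  expect_lt(abs(mesh_area(sph) - 4 * pi * 25) / (4 * pi * 25), 0.02)
})

test_that("a profile tapering onto the axis closes the apex watertight", {
  prof <- interpolate_bspline(rbind(c(2, 0, 0), c(1.5, 0, 3), c(0, 0, 6)))
  m <- tessellate(revolve_profile(prof), 32, 16)
  # apex: single welded vertex at the top, but the bottom stays open
  expect_equal(max(m$vertices[, 3]), 6, tolerance = 1e-9)
  expect_equal(sum(abs(m$vertices[, 3] - 6) < 1e-9), 1L)
})

test_that("profiles crossing the axis are rejected", {
  prof <- bspline_curve(rbind(c(-1, 0, 0), c(2, 0, 6)), degree = 1)
  expect_error(revolve_profile(prof), "crosses")
})

test_that("sphere tessellations are watertight and refine monotonically", {
  m1 <- sphere_mesh(5, 32, 24)
  m2 <- sphere_mesh(5, 64, 48)
  expect_true(mesh_is_closed(m1))
  expect_true(mesh_is_closed(m2))
  dev <- function(m) max(abs(sqrt(rowSums(m$vertices^2)) - 5))
  # vertices are exact evaluations, so radial deviation reflects the
  # profile interpolant, not the grid; area error must shrink instead
  err <- function(m) abs(mesh_area(m) - 4 * pi * 25)
  expect_lt(err(m2), err(m1))
  expect_error(tessellate(revolve_profile(
    bspline_curve(rbind(c(1, 0, 0), c(1, 0, 1)), degree = 1)), 2, 5),
    ">= 3")
})
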