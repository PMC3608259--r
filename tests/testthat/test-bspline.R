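test_that("degree-1 curves interpolate linearly and clamped ends are exact", {
  seg <- bspline_curve(rbind(c(0, 0, 0), c(2, 0, 0)), degree = 1)
  expect_equal(evaluate_curve(seg, 0.5), matrix(c(1, 0, 0), 1), tolerance = 1e-12)
  # clamped endpoint property for random curves, degrees 1-3
  set.seed(101)
  for (d in 1:3) {
    for (rep in 1:5) {
      P <- matrix(stats::rnorm((d + 2) * 3), d + 2L, 3L)
      crv <- bspline_curve(P, degree = d)
      ends <- evaluate_curve(crv, c(0, 1))
      expect_equal(ends[1, ], P[1, ], tolerance = 1e-9)
      expect_equal(ends[2, ], P[nrow(P), ], tolerance = 1e-9)
    }
  }
})

test_that("parameters outside [0,1] are rejected for open curves", {
  crv <- bspline_curve(matrix(stats::rnorm(12), 4, 3))
  expect_error(evaluate_curve(crv, 1.2), "outside")
  expect_error(evaluate_curve(crv, -0.1), "outside")
})

test_that("closed curves are periodic and smooth across the seam", {
  set.seed(7)
  th <- (0:7) / 8 * 2 * pi
  oct <- cbind(10 * cos(th), 10 * sin(th), 0)
  crv <- bspline_curve(oct, degree = 3, closed = TRUE)
  tt <- stats::runif(20)
  expect_equal(evaluate_curve(crv, tt), evaluate_curve(crv, tt + 1),
               tolerance = 1e-9)
  expect_equal(evaluate_curve(crv, tt), evaluate_curve(crv, tt - 2),
               tolerance = 1e-9)
})

test_that("closed cubic through octagon corners stays near a circle", {
  # dense-sampling oracle: best-fit circle radius = mean sampled radius
  th <- (0:7) / 8 * 2 * pi
  oct <- cbind(10 * cos(th), 10 * sin(th), 0)
  crv <- bspline_curve(oct, degree = 3, closed = TRUE)
  p <- evaluate_curve(crv, (0:4095) / 4096)
  rad <- sqrt(p[, 1]^2 + p[, 2]^2)
  expect_lt(max(abs(rad - mean(rad))), 0.5)
})

test_that("interpolating B-splines pass through their data points", {
  set.seed(12)
  Q <- cbind(sort(stats::runif(7, 0, 10)), stats::rnorm(7), stats::rnorm(7))
  crv <- interpolate_bspline(Q)
  seg <- sqrt(rowSums(diff(Q)^2))
  u <- c(0, cumsum(seg)) / sum(seg)
  expect_equal(evaluate_curve(crv, u), Q, tolerance = 1e-8,
               ignore_attr = TRUE)
  # closed variant
  th <- (0:9) / 10 * 2 * pi
  ring <- cbind(4 * cos(th), 3 * sin(th), 0)
  crv2 <- interpolate_bspline(ring, closed = TRUE)
  segc <- sqrt(rowSums((rbind(ring[-1, ], ring[1, ]) - ring)^2))
  uc <- c(0, cumsum(segc))[1:10] / sum(segc)
  expect_equal(evaluate_curve(crv2, uc), ring, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("degenerate control nets are rejected", {
  expect_error(bspline_curve(matrix(1, 2, 3), degree = 3), "control points")
  expect_error(bspline_curve(rbind(c(0, 0, 0), c(NA, 0, 0)), degree = 1),
               "finite")
})
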