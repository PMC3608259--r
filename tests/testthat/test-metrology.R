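test_that("a cylinder measures as a constant-width degenerate tooth", {
  cyl <- cylinder_mesh(3, 20)
  m <- measure_mesh(cyl, "incisor")
  expect_equal(m$values$EQU, 6, tolerance = 0.05)
  expect_equal(m$values$CEJ, 6, tolerance = 0.05)
  expect_equal(m$values$RAD, 6, tolerance = 0.05)
  expect_equal(m$values$T_H, 20, tolerance = 0.05)
  # no furcation on a single tube
  expect_error(measure_mesh(cyl, "molar"), "furcation not found")
})

test_that("Dahlberg error matches hand evaluations and is scale-equivariant", {
  expect_equal(dahlberg_error(rbind(c(5, 5), c(7, 7), c(9, 9)))$S_D, 0)
  expect_equal(dahlberg_error(rbind(c(1, 2), c(3, 3)))$S_D, 0.5)
  expect_equal(dahlberg_error(list(c(1, 2), c(3, 3)))$S_D, 0.5)
  expect_error(dahlberg_error(matrix(numeric(0), 0, 2)), "at least one")
  set.seed(3)
  pairs <- matrix(stats::rnorm(60, 10, 1), ncol = 2)
  s <- 2.5
  expect_equal(dahlberg_error(pairs * s)$S_D,
               s * dahlberg_error(pairs)$S_D, tolerance = 1e-12)
})

test_that("Dahlberg recovers an injected replicate error", {
  set.seed(21)
  truth <- stats::runif(500, 5, 25)
  pairs <- cbind(truth + stats::rnorm(500, 0, 0.4),
                 truth + stats::rnorm(500, 0, 0.4))
  expect_equal(dahlberg_error(pairs)$S_D, 0.4, tolerance = 0.05)
})

test_that("scale calibration is exact on proportional data and robust to noise", {
  x <- c(10, 15, 22, 8, 30)
  expect_equal(estimate_scale(x, x)$factor, 1, tolerance = 1e-12)
  cal <- estimate_scale(x, x / 0.313854)
  expect_equal(cal$factor, 0.313854, tolerance = 1e-9)
  expect_lt(cal$residual_rms, 1e-9)
  set.seed(5)
  ref <- stats::runif(100, 5, 25)
  tgt <- ref / 0.5 + stats::rnorm(100, 0, 0.1)
  expect_equal(estimate_scale(ref, tgt)$factor, 0.5, tolerance = 0.02)
  expect_error(estimate_scale(1:3, 1:4), "equal length")
  expect_error(estimate_scale(c(1, -2), c(1, 2)), "positive")
})

test_that("in-vivo records are restricted to crown measures", {
  expect_error(tooth_measures("2.1", "in_vivo", list(T_H = 23)), "crown")
  ok <- tooth_measures("2.1", "in_vivo", list(EQU = 8.5, C_H = 10.5))
  expect_s3_class(ok, "tooth_measures")
})

test_that("identical methods give a degenerate Wilcoxon at p = 1", {
  teeth <- sprintf("%d.%d", rep(1:4, each = 5), rep(1:5, 4))
  tab <- rbind(
    data.frame(tooth_id = teeth, method = "PAN", parameter = "EQU",
               value_mm = seq(7, 9, length.out = 20)),
    data.frame(tooth_id = teeth, method = "CBCT", parameter = "EQU",
               value_mm = seq(7, 9, length.out = 20)))
  rep_ <- compare_methods(tab)
  overall <- rep_$pairwise[rep_$pairwise$scope == "overall", ]
  expect_equal(overall$p, 1)
  expect_equal(overall$flag, "degenerate")
})

test_that("a shifted method is detected and scopes are populated", {
  set.seed(9)
  teeth <- sprintf("%d.%d", rep(1:4, each = 7), rep(1:7, 4))
  base <- stats::runif(28, 6, 10)
  tab <- rbind(
    data.frame(tooth_id = teeth, method = "PAN", parameter = "EQU",
               value_mm = base + stats::rnorm(28, 0, 0.2)),
    data.frame(tooth_id = teeth, method = "CBCT", parameter = "EQU",
               value_mm = base + 1.0 + stats::rnorm(28, 0, 0.2)))
  rep_ <- compare_methods(tab)
  overall <- rep_$pairwise[rep_$pairwise$scope == "overall", ]
  expect_lt(overall$p, 0.001)
  expect_true(all(c("arch: upper", "arch: lower") %in% rep_$pairwise$scope))
  expect_true(any(grepl("group: molar", rep_$pairwise$scope)))
  expect_true(any(grepl("values by method", rep_$kruskal$test)))
  expect_true(all(c("PAN", "CBCT", "diff: CBCT vs PAN") %in%
                    rep_$normality$series))
})

test_that("scanty strata are flagged, not fatal", {
  tab <- rbind(
    data.frame(tooth_id = c("1.1", "3.6"), method = "PAN",
               parameter = "EQU", value_mm = c(8, 11)),
    data.frame(tooth_id = c("1.1", "3.6"), method = "CBCT",
               parameter = "EQU", value_mm = c(8.2, 11.3)))
  rep_ <- compare_methods(tab)
  expect_true(any(rep_$pairwise$flag == "insufficient data") ||
                all(is.finite(rep_$pairwise$p)))
  expect_error(compare_methods(tab[tab$method == "PAN", ]), "2 methods")
})

test_that("measurement tables validate their schema and round-trip as CSV", {
  tab <- data.frame(tooth_id = "2.1", method = "PAN", parameter = "EQU",
                    value_mm = 8.5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_measurement_table(tab, p)
  expect_equal(read_measurement_table(p)$value_mm, 8.5)
  expect_error(write_measurement_table(tab[, -4], p), "lacks columns")
  expect_error(toothrecon:::validate_measurement_table(rbind(tab, tab)), "duplicate")
  bad <- tab; bad$value_mm <- -1
  expect_error(toothrecon:::validate_measurement_table(bad), "positive")
})
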