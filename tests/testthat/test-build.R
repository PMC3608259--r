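test_that("parameter records enforce their anatomical invariants", {
  expect_error(monoradicular_params(23, 23, 6.3, 8.5, 4.2), "C_H")
  expect_error(monoradicular_params(23, 10, 6.3, 5.5, 4.2), "CEJ")
  expect_error(monoradicular_params(23, 10, 6.3, 8.5, 7.0), "RAD")
  expect_error(monoradicular_params(23, 10, -1, 8.5, 4.2), "positive")
  expect_error(multiradicular_params(11, 9, 8, 7, 7.5, 20, 3.5, 3.2), "MC_H")
  expect_error(multiradicular_params(11, 9, 7.5, 7, 21, 20, 3.5, 3.2,
                                     PRAD = 3), "PRAD")
  expect_error(multiradicular_params(11, 9, 7.5, 7, 21, 20, 3.5, 3.2,
                                     H_FURC = 14), "H_FURC")
})

test_that("templates are valid and unknown classes are rejected", {
  for (cls in c("incisor", "molar")) {
    tpl <- default_template(cls)
    expect_true(all(unlist(tpl$ratios) > 0 & unlist(tpl$ratios) <= 2))
  }
  expect_true(default_template("molar")$ratios$furcation_frac < 1)
  expect_error(default_template("premolar"), "unknown tooth class")
  expect_error(build_monoradicular(incisor_params_ref(),
                                   default_template("molar")), "mismatch")
})

test_that("the reference incisor honours its control parameters", {
  model <- build_monoradicular(incisor_params_ref())
  expect_true(mesh_is_closed(model$mesh))
  bb <- mesh_bbox(model$mesh)
  expect_equal(bb[2, 3] - bb[1, 3], 23.0, tolerance = 0.1)
  zl <- seq(bb[1, 3] + 0.05, bb[2, 3] - 0.05, length.out = 200)
  w <- toothrecon:::slice_widths(model$mesh, zl)
  crown <- zl > 0
  expect_equal(max(w[crown], na.rm = TRUE), 8.5, tolerance = 0.1)
  m <- measure_mesh(model$mesh, "incisor")
  expect_params_recovered(m, incisor_params_ref())
})

test_that("the reference molar honours heights, widths and furcation", {
  model <- build_multiradicular(molar_params_ref())
  expect_true(mesh_is_closed(model$mesh))
  m <- measure_mesh(model$mesh, "molar")
  expect_params_recovered(m, molar_params_ref())
  # mesial axial extent
  v <- model$mesh$vertices
  mes <- v[v[, 1] > 0, ]
  expect_equal(max(mes[, 3]) - min(mes[, 3]), 21.0, tolerance = 0.15)
  # two distinct root contours 2 mm below the furcation
  furc <- -13 + 11
  s <- toothrecon:::mesh_slice(model$mesh, furc - 2 + 1e-4, contours = TRUE)
  expect_equal(s$n_contours, 2L)
  # mesial root width at half mesial root length
  z_half <- -13.5 + (furc - (-13.5)) / 2
  s2 <- toothrecon:::mesh_slice(model$mesh, z_half + 1e-4, contours = TRUE)
  mespts <- s2$points[s2$contour == which(vapply(
    seq_len(s2$n_contours),
    function(ci) mean(s2$points[s2$contour == ci, 1]) > 0, logical(1)))[1], ]
  expect_equal(max(mespts[, 1]) - min(mespts[, 1]), 3.5, tolerance = 0.1)
})

test_that("a palatal root yields a three-rooted watertight build", {
  p <- multiradicular_params(EQU = 10.5, CEJ = 8.8, MC_H = 7.2, DC_H = 7.0,
                             MT_H = 19.5, DT_H = 19.0, MRAD = 3.2,
                             DRAD = 3.0, PRAD = 3.6, PT_H = 20.0,
                             H_FURC = 9.0)
  model <- build_multiradicular(p)
  expect_true(mesh_is_closed(model$mesh))
  furc <- max(7.2 - 19.5, 7.0 - 19.0) + 9.0
  s <- toothrecon:::mesh_slice(model$mesh, furc - 1.5 + 1e-4, contours = TRUE)
  expect_equal(s$n_contours, 3L)
  m <- measure_mesh(model$mesh, "molar")
  expect_true(all(c("PRAD", "PT_H") %in% names(m$values)))
  expect_equal(m$values$PRAD, 3.6, tolerance = 0.1)
  expect_equal(m$values$PT_H, 20.0, tolerance = 0.15)
})

test_that("crown width and axial extent respond monotonically to EQU and T_H", {
  base <- incisor_params_ref()
  widths <- heights <- numeric(0)
  for (s in c(0.9, 1.0, 1.1)) {
    p1 <- monoradicular_params(base$T_H, base$C_H, base$CEJ,
                               base$EQU * s, base$RAD)
    widths <- c(widths, measure_mesh(build_monoradicular(
      p1, resolution = 48)$mesh, "incisor")$values$EQU)
    p2 <- monoradicular_params(base$T_H * s, base$C_H, base$CEJ,
                               base$EQU, base$RAD)
    bb <- mesh_bbox(build_monoradicular(p2, resolution = 48)$mesh)
    heights <- c(heights, bb[2, 3] - bb[1, 3])
  }
  expect_true(all(diff(widths) > 0))
  expect_true(all(diff(heights) > 0))
})

test_that("building is equivariant under uniform scaling", {
  p <- incisor_params_ref()
  m1 <- build_monoradicular(p, resolution = 48)$mesh
  s <- 1.3
  p2 <- monoradicular_params(p$T_H * s, p$C_H * s, p$CEJ * s, p$EQU * s,
                             p$RAD * s)
  m2 <- build_monoradicular(p2, resolution = 48)$mesh
  expect_equal(m2$vertices, m1$vertices * s, tolerance = 1e-6)
})
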