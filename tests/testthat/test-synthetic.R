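test_that("the noise-free limit reproduces truth exactly", {
  quiet_noise <- noise_model(landmark_sd = 0,
                             pan_magnification = c(height = 1, width = 1),
                             cbct_scale = 1,
                             mesh_perturbation_amplitude = 0)
  roster <- default_roster(full = FALSE)
  patient <- generate_patient(1, list(noise = quiet_noise, roster = roster,
                                      anatomical_cv = 0, replicates = 2,
                                      resolution = 32))
  t21 <- patient$teeth[["2.1"]]
  expect_identical(t21$segmented$vertices, t21$truth$mesh$vertices)
  truth <- unlist(unclass(roster[[1]]$params))
  for (m in c("in_vivo", "PAN", "CBCT")) {
    sub <- patient$table[patient$table$method == m &
                           patient$table$tooth_id == "2.1", ]
    expect_equal(sub$value_mm,
                 unname(truth[sub$parameter]), tolerance = 1e-12)
  }
})

test_that("generation is bit-identical under the same seed", {
  cfg <- list(roster = default_roster(full = FALSE), resolution = 32)
  p1 <- generate_patient(7, cfg)
  p2 <- generate_patient(7, cfg)
  expect_identical(p1$table, p2$table)
  expect_identical(p1$teeth[["3.6"]]$segmented$vertices,
                   p2$teeth[["3.6"]]$segmented$vertices)
  expect_identical(p1$teeth[["2.1"]]$volume$values,
                   p2$teeth[["2.1"]]$volume$values)
  p3 <- generate_patient(8, cfg)
  expect_false(identical(p1$table$value_mm, p3$table$value_mm))
})

test_that("mesh perturbation hits the requested RMS and decorrelates across seeds", {
  m <- build_monoradicular(incisor_params_ref(), resolution = 40)$mesh
  expect_identical(perturb_mesh(m, 0, 5, 1)$vertices, m$vertices)
  p1 <- perturb_mesh(m, 0.5, 5, 11)
  d1 <- p1$vertices - m$vertices
  expect_equal(sqrt(mean(rowSums(d1^2))), 0.5, tolerance = 0.05)
  expect_true(mesh_is_closed(p1))
  p2 <- perturb_mesh(m, 0.5, 5, 12)
  d2 <- p2$vertices - m$vertices
  expect_lt(abs(stats::cor(as.vector(d1), as.vector(d2))), 0.1)
})

test_that("measurement tables carry replicates, noise and magnification", {
  roster <- default_roster(full = TRUE)
  # zero noise, two replicates: Dahlberg is exactly zero
  nm0 <- noise_model(landmark_sd = 0)
  t0 <- make_measurement_table(roster, "PAN", nm0, replicates = 2, seed = 3)
  wide <- merge(t0[t0$replicate == 1, ], t0[t0$replicate == 2, ],
                by = c("tooth_id", "parameter"))
  expect_equal(dahlberg_error(cbind(wide$value_mm.x, wide$value_mm.y))$S_D, 0)
  # PAN magnification on heights is recovered by scale calibration
  nm <- noise_model(landmark_sd = 0.05,
                    pan_magnification = c(height = 1.2, width = 1.0),
                    cbct_scale = 1)
  pan <- make_measurement_table(roster, "PAN", nm, replicates = 1, seed = 4)
  cbct <- make_measurement_table(roster, "CBCT", nm, replicates = 1, seed = 5)
  hsel <- pan$parameter %in% toothrecon:::height_params
  mrg <- merge(cbct, pan, by = c("tooth_id", "parameter"))
  mh <- mrg[mrg$parameter %in% toothrecon:::height_params, ]
  cal <- estimate_scale(mh$value_mm.x, mh$value_mm.y)
  expect_equal(cal$factor, 1 / 1.2, tolerance = 0.02)
  expect_error(make_measurement_table(roster, "MRI", nm), "unknown method")
  # in vivo: crown parameters only
  iv <- make_measurement_table(roster, "in_vivo", nm, replicates = 1, seed = 6)
  expect_true(all(iv$parameter %in% toothrecon:::crown_params))
})

test_that("pooled replicate noise satisfies the sub-millimetre repeatability bound", {
  set.seed(33)
  roster <- default_roster(full = TRUE)
  nm <- noise_model(landmark_sd = 0.35, cbct_scale = 1)
  pairs <- do.call(rbind, lapply(c("PAN", "in_vivo"), function(m) {
    tab <- make_measurement_table(roster, m, nm, replicates = 2, seed = 13)
    wide <- merge(tab[tab$replicate == 1, ], tab[tab$replicate == 2, ],
                  by = c("tooth_id", "parameter"))
    cbind(wide$value_mm.x, wide$value_mm.y)
  }))
  expect_gt(nrow(pairs), 200)
  sd_hat <- dahlberg_error(pairs)$S_D
  expect_lt(abs(sd_hat - 0.35), 0.05)
  expect_lt(sd_hat, 1)
})

test_that("invalid rosters are reported with the offending tooth", {
  expect_error(generate_patient(1, list(roster = list(list(tooth_id = "9.9")))),
               "invalid roster entry")
})
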