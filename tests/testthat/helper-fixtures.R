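# shared fixtures, generated in code

circle_section <- function(r, z, n = 12L) {
  th <- (seq_len(n) - 1L) / n * 2 * pi
  interpolate_bspline(cbind(r * cos(th), r * sin(th), z), closed = TRUE)
}

sphere_mesh <- function(r = 8, nu = 64L, nv = 48L) {
  th <- seq(0, pi, length.out = 25L)
  prof <- interpolate_bspline(cbind(r * sin(th), 0, -r * cos(th)))
  tessellate(revolve_profile(prof), nu, nv)
}

cylinder_mesh <- function(r = 3, h = 20, n = 48L, nz = 10L) {
  th <- (seq_len(n) - 1L) / n * 2 * pi
  rings <- lapply(seq(0, h, length.out = nz), function(z)
    cbind(r * cos(th), r * sin(th), z))
  toothrecon:::mesh_from_rings(rings, bottom = "fan", top = "fan")
}

incisor_params_ref <- function() {
  monoradicular_params(T_H = 23.0, C_H = 10.5, CEJ = 6.3, EQU = 8.5,
                       RAD = 4.2)
}

molar_params_ref <- function() {
  multiradicular_params(EQU = 11.0, CEJ = 9.0, MC_H = 7.5, DC_H = 7.0,
                        MT_H = 21.0, DT_H = 20.0, MRAD = 3.5, DRAD = 3.2,
                        H_FURC = 11.0)
}

random_incisor_params <- function() {
  T_H <- stats::runif(1, 18, 28)
  C_H <- stats::runif(1, 0.35, 0.5) * T_H
  EQU <- stats::runif(1, 7, 10)
  CEJ <- stats::runif(1, 0.65, 0.85) * EQU
  RAD <- stats::runif(1, 0.55, 0.9) * CEJ
  monoradicular_params(T_H, C_H, CEJ, EQU, RAD)
}

random_molar_params <- function() {
  MT_H <- stats::runif(1, 18, 23)
  DT_H <- MT_H * stats::runif(1, 0.92, 1)
  MC_H <- stats::runif(1, 0.30, 0.42) * MT_H
  DC_H <- stats::runif(1, 0.30, 0.42) * DT_H
  EQU <- stats::runif(1, 9.5, 12)
  CEJ <- stats::runif(1, 0.75, 0.9) * EQU
  H_FURC <- stats::runif(1, 0.5, 0.85) * min(MT_H - MC_H, DT_H - DC_H)
  multiradicular_params(EQU, CEJ, MC_H, DC_H, MT_H, DT_H,
                        MRAD = stats::runif(1, 2.8, 4),
                        DRAD = stats::runif(1, 2.8, 4), H_FURC = H_FURC)
}

# recovery check at the parameter-faithfulness contract tolerance
expect_params_recovered <- function(measured, params,
                                    rel = 0.02, abs_mm = 0.1) {
  pv <- unlist(Filter(Negate(is.null), unclass(params)))
  mv <- unlist(measured$values)[names(pv)]
  tol <- pmax(rel * pv, abs_mm)
  expect_true(all(is.finite(mv)))
  expect_true(all(abs(mv - pv) <= tol),
              label = paste0("parameter recovery within tolerance (worst: ",
                             names(which.max(abs(mv - pv) / tol)), ")"))
}

# signed-distance volume of a sphere on a regular grid
sphere_sdf_volume <- function(r = 8, n = 64L, spacing = 1) {
  g <- (seq_len(n) - (n + 1) / 2) * spacing
  gr <- expand.grid(x = g, y = g, z = g)
  sdf <- sqrt(gr$x^2 + gr$y^2 + gr$z^2) - r
  scalar_volume(array(sdf, dim = c(n, n, n)), spacing = rep(spacing, 3),
                origin = rep(g[1], 3))
}

# asymmetric registration fixture: the idealised tooth templates are
# centrally symmetric about their long axis, which makes pose recovery
# ill-posed (a half-turn is an exact self-map); a smooth deterministic
# warp removes the symmetry without adding any vertex-level noise
asymmetric_test_mesh <- function(resolution = 32L) {
  perturb_mesh(build_monoradicular(incisor_params_ref(),
                                   resolution = resolution)$mesh,
               amplitude = 0.6, wavelength = 6, seed = 99L)
}

random_rigid <- function(max_angle = 30 * pi / 180, max_trans = 10) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0.1 * max_angle, max_angle)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  rigid_transform(R, stats::runif(3, -max_trans, max_trans))
}
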