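#' Measurement parameter records for the two built tooth classes
#'
#' Bundles the panoramic-radiograph control measurements (mm) for a
#' single-rooted or multi-rooted tooth, with validation of the anatomical
#' invariants the builders rely on.
#'
#' @param T_H total tooth height, apex to cusp (mm)
#' @param C_H crown height, cervical line to cusp (mm)
#' @param CEJ cement-enamel junction width: narrowest cervical width (mm)
#' @param EQU equator width: widest part of the crown (mm)
#' @param RAD root width at half root length (mm)
#' @return a \code{monoradicular_params} object
#' @export
monoradicular_params <- function(T_H, C_H, CEJ, EQU, RAD) {
  p <- list(T_H = T_H, C_H = C_H, CEJ = CEJ, EQU = EQU, RAD = RAD)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("parameter %s must be a single positive number", nm))
    }
  }
  if (p$C_H >= p$T_H) stop("invalid C_H: crown height C_H must be < total height T_H")
  if (p$RAD > p$CEJ) stop("invalid RAD: root width RAD must be <= CEJ width")
  if (p$CEJ > p$EQU) stop("invalid CEJ: CEJ width must be <= equator width EQU")
  structure(p, class = c("monoradicular_params", "tooth_params"))
}

#' @param EQU,CEJ as for the single-rooted class (mm)
#' @param MC_H,DC_H mesial / distal crown height: cusp to cervical line (mm)
#' @param MT_H,DT_H mesial / distal tooth height: cusp to root apex (mm)
#' @param MRAD,DRAD mesial / distal root width at half root length (mm)
#' @param PRAD,PT_H optional palatal root width and height (third root)
#' @param H_FURC optional furcation-to-(shorter-root)-apex distance (mm);
#'   defaults to the template's furcation fraction of the shorter root.
#' @rdname monoradicular_params
#' @export
multiradicular_params <- function(EQU, CEJ, MC_H, DC_H, MT_H, DT_H,
                                  MRAD, DRAD, PRAD = NULL, PT_H = NULL,
                                  H_FURC = NULL) {
  p <- list(EQU = EQU, CEJ = CEJ, MC_H = MC_H, DC_H = DC_H,
            MT_H = MT_H, DT_H = DT_H, MRAD = MRAD, DRAD = DRAD,
            PRAD = PRAD, PT_H = PT_H, H_FURC = H_FURC)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (is.null(v)) next
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("parameter %s must be a single positive number", nm))
    }
  }
  if (p$MC_H >= p$MT_H) stop("invalid MC_H: must be < mesial tooth height MT_H")
  if (p$DC_H >= p$DT_H) stop("invalid DC_H: must be < distal tooth height DT_H")
  if (is.null(p$PRAD) != is.null(p$PT_H)) {
    stop("invalid PRAD/PT_H: a palatal root needs both PRAD and PT_H")
  }
  root_lens <- c(p$MT_H - p$MC_H, p$DT_H - p$DC_H)
  if (!is.null(p$H_FURC) && p$H_FURC >= min(root_lens)) {
    stop("invalid H_FURC: must be smaller than the shortest root length")
  }
  structure(p, class = c("multiradicular_params", "tooth_params"))
}

#' @export
print.tooth_params <- function(x, ...) {
  vals <- unlist(Filter(Negate(is.null), unclass(x)))
  cat(sprintf("<%s>\n", class(x)[1]))
  print(round(vals, 3))
  invisible(x)
}

#' @export
print.tooth_model <- function(x, ...) {
  cat(sprintf("<tooth_model: %s, template '%s'>\n", x$tooth_class,
              x$template_id))
  print(x$mesh)
  invisible(x)
}

new_tooth_model <- function(mesh, params, template, tooth_class) {
  if (!mesh_is_closed(mesh)) {
    stop("internal error: assembled tooth mesh is not closed")
  }
  structure(list(mesh = mesh, params = params,
                 template_id = template$id, tooth_class = tooth_class,
                 axis_frame = "origin at CEJ centroid; +z occlusal, +x mesial, +y buccal"),
            class = "tooth_model")
}

# evaluate a section stack as rings at prescribed z levels, blending
# linearly between adjacent sections: every section is reproduced exactly
# at its own level and widths never overshoot between sections (a spline
# through all sections can bulge past a prescribed extremum, which would
# corrupt the width parameters the builders must honour exactly).
loft_rings_at_z <- function(sections, z_sections, z_out, nu) {
  us <- (seq_len(nu) - 1L) / nu
  ring_of <- lapply(sections, function(s) evaluate_curve(s, us))
  K <- length(sections)
  lapply(z_out, function(z) {
    i <- findInterval(z, z_sections, rightmost.closed = TRUE)
    i <- min(max(i, 1L), K - 1L)
    w <- (z - z_sections[i]) / (z_sections[i + 1L] - z_sections[i])
    w <- min(max(w, 0), 1)
    (1 - w) * ring_of[[i]] + w * ring_of[[i + 1L]]
  })
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# cosine-eased monotone segment interpolation through (xk, zk) knots:
# C1-flat at every knot, never overshoots, attains each knot value exactly.
cosine_knot_interp <- function(xk, zk) {
  function(x) {
    i <- findInterval(x, xk, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(xk) - 1L)
    t <- (x - xk[i]) / (xk[i + 1L] - xk[i])
    zk[i] + (zk[i + 1L] - zk[i]) * (1 - cos(pi * pmin(pmax(t, 0), 1))) / 2
  }
}

#' Build a single-rooted parametric tooth
#'
#' Assembles a watertight incisor-class mesh in the canonical frame
#' (origin at the CEJ centroid, +z occlusal, +x mesial, +y buccal):
#' the root is a loft through closed B-spline cross sections (an apex-band
#' section, the mid-root section scaled to RAD, a cervical collar and the
#' CEJ section), pole-welded at the apex; the crown is a connection loft
#' from the CEJ section to the equator section (width EQU) topped by a dome
#' of four Coons patches bounded by B-spline meridians meeting at the
#' incisal tip at height C-H.
#'
#' @param params a \code{monoradicular_params} record (mm)
#' @param template a \code{shape_template} for class \code{"incisor"}
#' @param resolution points around a cross section (rounded up to a
#'   multiple of 4); axial ring counts scale with it.
#' @return a \code{tooth_model}
#' @export
build_monoradicular <- function(params, template = default_template("incisor"),
                                resolution = 64L) {
  stopifnot(inherits(params, "monoradicular_params"),
            inherits(template, "shape_template"))
  if (template$tooth_class != "incisor") {
    stop("template class mismatch: need an incisor template")
  }
  r <- template$ratios
  nu <- as.integer(4L * ceiling(resolution / 4))
  RL <- params$T_H - params$C_H
  z_apex <- -RL
  z_tipband <- -RL * (1 - r$apex_band_frac)
  z_mid <- -RL / 2
  z_collar <- -r$collar_drop_frac * RL
  h_equ <- r$equator_height_frac * params$C_H
  sec <- function(w, z, exponent = r$root_shape_exponent,
                  depth_ratio = r$root_depth_ratio) {
    calibrated_section(exponent, w, depth_ratio * w, z)
  }
  cervix <- sec(params$CEJ, 0)
  root_secs <- list(sec(r$apex_tip_frac * params$RAD, z_tipband),
                    sec(params$RAD, z_mid),
                    sec(r$collar_bulge * params$CEJ, z_collar),
                    cervix)
  z_secs <- c(z_tipband, z_mid, z_collar, 0)
  nv_root <- max(12L, as.integer(nu * 0.45))
  z_root <- sort(unique(c(seq(z_tipband, 0, length.out = nv_root),
                          z_mid, z_collar)))
  root <- mesh_from_rings(loft_rings_at_z(root_secs, z_secs, z_root, nu),
                          bottom = "pole", bottom_point = c(0, 0, z_apex))
  # connection loft CEJ -> equator
  equ <- calibrated_section(r$crown_shape_exponent, params$EQU,
                            r$crown_depth_ratio * params$EQU, h_equ)
  z_low <- seq(0, h_equ, length.out = max(6L, as.integer(nu / 8)))
  lower_crown <- mesh_from_rings(
    loft_rings_at_z(list(cervix, equ), c(0, h_equ), z_low, nu))
  # dome: four Coons patches from the equator rim to the incisal tip
  tip <- c(0, 0, params$C_H)
  mer <- lapply(c(0, 0.25, 0.5, 0.75), function(u0) {
    p0 <- evaluate_curve(equ, u0)[1, ]
    f <- c(0, 0.4, 0.75, 1)
    s <- c(1, r$dome_bulge, 0.45, 0)
    pts <- cbind(p0[1] * s, p0[2] * s, h_equ + f * (params$C_H - h_equ))
    interpolate_bspline(pts)
  })
  nv_dome <- max(8L, as.integer(nu / 4))
  dome <- lapply(1:4, function(k) {
    knext <- if (k == 4L) 1L else k + 1L
    b1 <- function(t) evaluate_curve(equ, (k - 1) / 4 + t / 4)[1, ]
    b2 <- function(t) evaluate_curve(mer[[knext]], t)[1, ]
    b3 <- function(t) tip
    b4 <- function(t) evaluate_curve(mer[[k]], 1 - t)[1, ]
    patch <- coons_patch(list(b1, b2, b3, b4))
    g <- expand.grid(u = seq(0, 1, length.out = nu / 4 + 1L),
                     v = seq(0, 1, length.out = nv_dome))
    mesh_from_grid(array(eval_surface(patch, g$u, g$v),
                         dim = c(nu / 4 + 1L, nv_dome, 3L)))
  })
  mesh <- do.call(merge_meshes, c(list(root, lower_crown), dome))
  new_tooth_model(mesh, params, template, "incisor")
}

# split a closed ring (nu x 3) into sector loops through its centroid;
# cuts are u-fractions that must land on ring vertices.
sector_loops <- function(ring, cuts) {
  nu <- nrow(ring)
  idx <- round(cuts * nu) + 1L
  if (any(abs(cuts * nu - round(cuts * nu)) > 1e-9)) {
    stop("sector cuts must align with ring vertices")
  }
  center <- c(colMeans(ring[, 1:2, drop = FALSE]), ring[1, 3])
  k <- length(idx)
  lapply(seq_len(k), function(j) {
    a <- idx[j]
    b <- idx[if (j == k) 1L else j + 1L]
    sel <- if (a < b) a:b else c(a:nu, 1:b)
    rbind(ring[sel, , drop = FALSE], center)
  })
}

# morphing ring stack for one root: from its top loop (at the furcation
# plane) through revolution-profile circular sections to a pole-welded apex
root_stack <- function(loop, rad, z_apex, z_furc, tip_frac, n_rings) {
  m <- nrow(loop)
  cen <- colMeans(loop[, 1:2, drop = FALSE])
  phi <- atan2(loop[, 2] - cen[2], loop[, 1] - cen[1])
  # the centroid vertex (last) gets the bisector of the wrap-around gap
  gap <- (phi[1] - phi[m - 1L]) %% (2 * pi)
  phi[m] <- phi[m - 1L] + gap / 2
  r_eq <- mean(sqrt((loop[, 1] - cen[1])^2 + (loop[, 2] - cen[2])^2))
  Lr <- z_furc - z_apex
  z_half <- z_apex + Lr / 2
  z_tip <- z_apex + 0.04 * Lr
  zs <- sort(unique(c(seq(z_tip, z_furc, length.out = n_rings), z_half)))
  rfun <- stats::splinefun(c(z_tip, z_half, z_furc),
                           c(tip_frac * rad / 2, rad / 2, r_eq),
                           method = "natural")
  rings <- lapply(zs, function(z) {
    beta <- if (z >= z_half) smoothstep((z_furc - z) / (z_furc - z_half)) else 1
    rr <- rfun(z)
    Cx <- cen[1] + rr * cos(phi)
    Cy <- cen[2] + rr * sin(phi)
    cbind((1 - beta) * loop[, 1] + beta * Cx,
          (1 - beta) * loop[, 2] + beta * Cy,
          z)
  })
  mesh_from_rings(rings, bottom = "pole",
                  bottom_point = c(cen[1], cen[2], z_apex))
}

# occlusal ridge ring: a thin two-cusp loop whose height profile attains
# the mesial and distal cusp heights exactly at +/- cusp_x
ridge_ring <- function(nu, EQU, MC_H, DC_H, r) {
  w_half <- r$ridge_edge_frac * EQU
  cusp_x <- r$cusp_x_frac * EQU
  delta <- r$ridge_halfwidth_frac * EQU
  fiss <- r$fissure_frac * min(MC_H, DC_H)
  zfun <- cosine_knot_interp(
    c(-w_half, -cusp_x, 0, cusp_x, w_half),
    c(r$ridge_end_drop * DC_H, DC_H, fiss, MC_H, r$ridge_end_drop * MC_H))
  n_half <- nu / 2L
  n_mid <- n_half + 1L - 8L
  xs_fwd <- c(seq(w_half, cusp_x, length.out = 5L),
              seq(cusp_x, -cusp_x, length.out = n_mid)[-1],
              seq(-cusp_x, -w_half, length.out = 5L)[-1])
  stopifnot(length(xs_fwd) == n_half + 1L)
  xs_bwd <- rev(xs_fwd)[2:n_half]
  y_fwd <- c(0, rep(delta, n_half - 1L), 0)
  ring <- rbind(cbind(xs_fwd, y_fwd, zfun(xs_fwd)),
                cbind(xs_bwd, -delta, zfun(xs_bwd)))
  stopifnot(nrow(ring) == nu)
  ring
}

#' Build a multi-rooted parametric tooth
#'
#' Assembles a watertight molar-class mesh: the crown is a loft from the
#' CEJ section through the equator (width EQU) to an occlusal rim, capped
#' by a morph onto a two-cusp ridge whose mesial and distal cusps attain
#' MC-H and DC-H; the root trunk lofts from the CEJ section down to the
#' furcation plane, where the trunk ring is split into sector loops (two,
#' or three when a palatal root is given) joined through shared septum
#' edges; each root then descends through revolution-profile circular
#' sections — width MRAD/DRAD/PRAD at half root length — to a pole-welded
#' apex at its own tooth height.
#'
#' @param params a \code{multiradicular_params} record (mm)
#' @param template a \code{shape_template} for class \code{"molar"}
#' @param resolution points around a cross section (rounded up to a
#'   multiple of 16).
#' @return a \code{tooth_model}
#' @export
build_multiradicular <- function(params, template = default_template("molar"),
                                 resolution = 64L) {
  stopifnot(inherits(params, "multiradicular_params"),
            inherits(template, "shape_template"))
  if (template$tooth_class != "molar") {
    stop("template class mismatch: need a molar template")
  }
  r <- template$ratios
  nu <- max(32L, as.integer(16L * ceiling(resolution / 16)))
  has_pal <- !is.null(params$PRAD)
  z_ap_m <- params$MC_H - params$MT_H
  z_ap_d <- params$DC_H - params$DT_H
  z_ap <- c(mesial = z_ap_m, distal = z_ap_d)
  rads <- c(mesial = params$MRAD, distal = params$DRAD)
  if (has_pal) {
    z_ap <- c(z_ap, palatal = max(params$MC_H, params$DC_H) - params$PT_H)
    rads <- c(rads, palatal = params$PRAD)
  }
  h_furc <- if (!is.null(params$H_FURC)) params$H_FURC
  else r$furcation_frac * (-max(z_ap_m, z_ap_d))
  z_furc <- max(z_ap_m, z_ap_d) + h_furc
  if (z_furc >= -0.05 * (-min(z_ap))) {
    stop("invalid H_FURC: furcation would reach the cervical line")
  }
  trunk_len <- -z_furc
  z_collar <- -r$collar_drop_frac * trunk_len
  sec <- function(w, z, exponent = r$trunk_shape_exponent,
                  depth_ratio = r$trunk_depth_ratio) {
    calibrated_section(exponent, w, depth_ratio * w, z)
  }
  cervix <- sec(params$CEJ, 0)
  trunk_secs <- list(sec(r$trunk_taper * params$CEJ, z_furc),
                     sec(r$collar_bulge * params$CEJ, z_collar),
                     cervix)
  nv_trunk <- max(8L, as.integer(nu / 5))
  z_trunk <- sort(unique(c(seq(z_furc, 0, length.out = nv_trunk), z_collar)))
  trunk_rings <- loft_rings_at_z(trunk_secs, c(z_furc, z_collar, 0),
                                 z_trunk, nu)
  trunk <- mesh_from_rings(trunk_rings)
  # sector split at the furcation plane
  cuts <- if (has_pal) c(0.25, 0.625, 0.875) else c(0.25, 0.75)
  loops <- sector_loops(trunk_rings[[1]], cuts)
  cx <- vapply(loops, function(L) mean(L[, 1]), numeric(1))
  cy <- vapply(loops, function(L) mean(L[, 2]), numeric(1))
  lab <- rep(NA_character_, length(loops))
  lab[which.max(cx)] <- "mesial"
  lab[which.min(cx)] <- "distal"
  if (has_pal) lab[is.na(lab)] <- "palatal"
  n_root_rings <- max(10L, as.integer(nu / 4))
  roots <- lapply(seq_along(loops), function(j) {
    root_stack(loops[[j]], rads[[lab[j]]], z_ap[[lab[j]]], z_furc,
               r$root_tip_frac, n_root_rings)
  })
  # crown: CEJ -> equator -> occlusal rim, then morph onto the cusp ridge
  min_ch <- min(params$MC_H, params$DC_H)
  h_equ <- r$equator_height_frac * min_ch
  h_rim <- r$rim_height_frac * min_ch
  equ_sec <- sec(params$EQU, h_equ, r$crown_shape_exponent,
                 r$crown_depth_ratio)
  rim_sec <- sec(r$rim_width_frac * params$EQU, h_rim,
                 r$crown_shape_exponent, r$crown_depth_ratio)
  z_crown <- sort(unique(c(seq(0, h_rim, length.out = nv_trunk), h_equ)))
  crown_rings <- loft_rings_at_z(list(cervix, equ_sec, rim_sec),
                                 c(0, h_equ, h_rim), z_crown, nu)
  crown <- mesh_from_rings(crown_rings)
  rim <- crown_rings[[length(crown_rings)]]
  ridge <- ridge_ring(nu, params$EQU, params$MC_H, params$DC_H, r)
  n_cap <- max(6L, as.integer(nu / 8))
  gam <- smoothstep(seq(0, 1, length.out = n_cap))
  cap_rings <- lapply(gam, function(g) (1 - g) * rim + g * ridge)
  # close the occlusal slit with a fan dipped to the central fissure, so
  # the cusp tips stay the highest points on their own sides
  fiss_z <- 0.98 * r$fissure_frac * min_ch
  cap <- mesh_from_rings(cap_rings, top = "fan",
                         top_point = c(0, 0, fiss_z))
  mesh <- do.call(merge_meshes, c(list(trunk, crown, cap), roots))
  new_tooth_model(mesh, params, template, "molar")
}
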