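#' Shape templates: fixed anatomical proportions
#'
#' The measured control parameters (heights and widths in mm) do not fully
#' determine a tooth shape; the remaining proportions — cross-section
#' roundness, crown depth relative to width, blend heights, inter-root
#' spacing, the default furcation fraction — are dimensionless constants
#' kept fixed across builds, in the spirit of population-average dental
#' anatomy. Template values are implementation constants of this package,
#' chosen to be anatomically plausible for a maxillary central incisor and
#' a mandibular first molar; they are not fitted to any patient.
#'
#' @param tooth_class \code{"incisor"} (monoradicular builder) or
#'   \code{"molar"} (multiradicular builder).
#' @return an immutable \code{shape_template} with named dimensionless
#'   ratios (all in (0, 2]); lengths expressed as fractions of the measured
#'   dimensions they scale.
#' @export
default_template <- function(tooth_class = c("incisor", "molar")) {
  if (length(tooth_class) == 1L && !tooth_class %in% c("incisor", "molar")) {
    stop(sprintf("unknown tooth class '%s' (supported: incisor, molar)",
                 tooth_class))
  }
  tooth_class <- match.arg(tooth_class)
  ratios <- if (tooth_class == "incisor") {
    list(
      crown_depth_ratio    = 0.75,  # crown depth (buccolingual) / EQU
      root_depth_ratio     = 0.90,  # root section depth / width
      equator_height_frac  = 0.32,  # equator level as fraction of C-H
      collar_bulge         = 1.04,  # cervical root collar width / CEJ
      collar_drop_frac     = 0.07,  # collar depth below CEJ / root length
      apex_tip_frac        = 0.06,  # last ring scale before the apex pole
      apex_band_frac       = 0.04,  # height of the apex taper band
      root_shape_exponent  = 1.80,  # superellipse exponent, root sections
      crown_shape_exponent = 2.00,  # superellipse exponent, crown sections
      dome_bulge           = 0.85   # crown dome meridian fullness
    )
  } else {
    list(
      crown_depth_ratio    = 0.95,
      trunk_depth_ratio    = 0.95,
      equator_height_frac  = 0.45,
      rim_height_frac      = 0.78,  # occlusal rim level / min cusp height
      rim_width_frac       = 0.85,
      collar_bulge         = 1.04,
      collar_drop_frac     = 0.07,
      furcation_frac       = 0.60,  # default H-FURC / shorter root length
      trunk_taper          = 0.80,  # trunk width at furcation / CEJ
      cusp_x_frac          = 0.30,  # cusp tip offset from midline / EQU
      ridge_edge_frac      = 0.40,  # occlusal ridge half extent / EQU
      fissure_frac         = 0.88,  # central fissure depth / min cusp height
      ridge_end_drop       = 0.93,  # ridge height at its ends / cusp height
      ridge_halfwidth_frac = 0.04,  # occlusal ridge half thickness / EQU
      root_tip_frac        = 0.06,
      crown_shape_exponent = 2.00,
      trunk_shape_exponent = 1.90
    )
  }
  bad <- names(ratios)[vapply(ratios, function(r)
    !(is.numeric(r) && r > 0 && r <= 2), logical(1))]
  if (length(bad)) stop("template ratios outside (0, 2]: ",
                        paste(bad, collapse = ", "))
  structure(list(id = paste0("default_", tooth_class),
                 tooth_class = tooth_class, ratios = ratios),
            class = "shape_template")
}

#' @export
print.shape_template <- function(x, ...) {
  cat(sprintf("<shape_template '%s' (%s)>\n", x$id, x$tooth_class))
  for (nm in names(x$ratios)) cat(sprintf("  %-22s %.3f\n", nm, x$ratios[[nm]]))
  invisible(x)
}

# Closed superellipse-like cross section with calibrated extents: the
# returned curve's dense-sampled x extent equals `width` and y extent
# equals `depth` exactly (control-point scaling is exact for B-splines).
calibrated_section <- function(exponent, width, depth, z,
                               center = c(0, 0), n_pts = 16L) {
  th <- (seq_len(n_pts) - 1L) / n_pts * 2 * pi
  e <- 2 / exponent
  px <- sign(cos(th)) * abs(cos(th))^e
  py <- sign(sin(th)) * abs(sin(th))^e
  crv <- interpolate_bspline(cbind(px, py, 0), closed = TRUE)
  s <- sample_curve(crv, 512L)
  ex <- max(s[, 1]) - min(s[, 1])
  ey <- max(s[, 2]) - min(s[, 2])
  cp <- crv$control_points
  cp[, 1] <- cp[, 1] * (width / ex) + center[1]
  cp[, 2] <- cp[, 2] * (depth / ey) + center[2]
  cp[, 3] <- z
  bspline_curve(cp, degree = crv$degree, closed = TRUE)
}
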