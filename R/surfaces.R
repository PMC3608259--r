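#' Parametric surfaces: lofts, Coons patches, surfaces of revolution
#'
#' All surfaces map the unit square (u, v) in \[0,1\]^2 to 3D points (mm).
#' Lofted surfaces interpolate each of their section curves exactly at the
#' section's v-level; Coons patches reproduce their four boundary curves;
#' revolution surfaces are rotationally symmetric about their axis, with
#' u the rotation fraction and v the profile parameter.
#'
#' @name parametric_surface
NULL

new_surface <- function(kind, eval_fn, generators, closed_u = FALSE) {
  structure(list(kind = kind, eval = eval_fn, generators = generators,
                 closed_u = closed_u),
            class = "parametric_surface")
}

#' @export
print.parametric_surface <- function(x, ...) {
  cat(sprintf("<parametric_surface: %s, %s in u>\n", x$kind,
              if (x$closed_u) "closed" else "open"))
  invisible(x)
}

#' Evaluate a parametric surface
#' @param surface a \code{parametric_surface}
#' @param u,v numeric vectors of equal length (or length 1, recycled), in
#'   \[0,1\].
#' @return matrix of 3D points (mm), one row per (u, v) pair.
#' @export
eval_surface <- function(surface, u, v) {
  n <- max(length(u), length(v))
  u <- rep_len(as.numeric(u), n)
  v <- rep_len(as.numeric(v), n)
  if (any(v < -1e-9 | v > 1 + 1e-9)) stop("v outside [0, 1]")
  if (!surface$closed_u && any(u < -1e-9 | u > 1 + 1e-9)) {
    stop("u outside [0, 1]")
  }
  p <- surface$eval(u, pmin(pmax(v, 0), 1))
  if (any(!is.finite(p))) stop("surface evaluation produced non-finite points")
  p
}

# signed area of the xy projection of a closed curve (dense polygon)
closed_curve_signed_area <- function(curve, n = 256L) {
  p <- sample_curve(curve, n)
  x <- p[, 1]; y <- p[, 2]
  nx <- c(2:n, 1L)
  0.5 * sum(x * y[nx] - x[nx] * y)
}

#' Loft a surface through an ordered stack of closed sections
#'
#' The surface interpolates every section: at the j-th section's v-level the
#' surface reproduces that section curve exactly. Between sections the
#' surface is a natural cubic spline (in v) through the section points,
#' evaluated per u. Sections are automatically re-oriented counter-clockwise
#' about +z so that windings are consistent.
#'
#' @param sections list of at least two closed \code{bspline_curve}s,
#'   ordered along the lofting direction.
#' @param v_levels optional increasing v-levels in \[0,1\] assigned to the
#'   sections; defaults to chord-length spacing of the section centroids
#'   (uniform if degenerate).
#' @return a \code{parametric_surface} of kind \code{"loft"}, closed in u.
#' @export
loft_sections <- function(sections, v_levels = NULL) {
  if (length(sections) < 2L) stop("need at least 2 sections")
  if (!all(vapply(sections, function(s)
    inherits(s, "bspline_curve") && s$closed, logical(1)))) {
    stop("all sections must be closed bspline_curve objects")
  }
  sections <- lapply(sections, function(s) {
    a <- closed_curve_signed_area(s)
    if (is.na(a) || abs(a) < 1e-12) s
    else if (a < 0) reverse_curve(s) else s
  })
  K <- length(sections)
  if (is.null(v_levels)) {
    cent <- t(vapply(sections, function(s) colMeans(sample_curve(s, 64L)),
                     numeric(3)))
    seg <- sqrt(rowSums((cent[-1, , drop = FALSE] - cent[-K, , drop = FALSE])^2))
    v_levels <- if (sum(seg) < 1e-9) seq(0, 1, length.out = K)
    else c(0, cumsum(seg)) / sum(seg)
  }
  if (length(v_levels) != K || is.unsorted(v_levels, strictly = TRUE)) {
    stop("v_levels must be strictly increasing, one per section")
  }
  eval_fn <- function(u, v) {
    uu <- unique(u)
    sec_pts <- lapply(sections, evaluate_curve, t = uu)  # K x (n_uu x 3)
    out <- matrix(NA_real_, length(u), 3L)
    if (K == 2L) {
      iu <- match(u, uu)
      w <- (v - v_levels[1]) / (v_levels[2] - v_levels[1])
      for (k in 1:3) {
        out[, k] <- (1 - w) * sec_pts[[1]][iu, k] + w * sec_pts[[2]][iu, k]
      }
      return(out)
    }
    for (i in seq_along(uu)) {
      sel <- u == uu[i]
      S <- t(vapply(sec_pts, function(m) m[i, ], numeric(3)))
      vv <- v[sel]
      for (k in 1:3) {
        out[sel, k] <- stats::spline(v_levels, S[, k], xout = vv,
                                     method = "natural")$y
      }
    }
    out
  }
  new_surface("loft", eval_fn, list(sections = sections, v_levels = v_levels),
              closed_u = TRUE)
}

#' Coons patch bounded by four curves
#'
#' Builds the bilinearly blended Coons surface whose restriction to each
#' edge of the unit square reproduces the corresponding boundary curve. The
#' four curves must form a closed loop: curve k ends where curve k+1 starts
#' (within \code{tol}), and curve 4 ends at the start of curve 1. Degenerate
#' boundary curves (a constant point, e.g. a crown tip) are allowed.
#'
#' @param boundary list of 4 \code{bspline_curve}s in loop order.
#' @param tol endpoint closure tolerance (mm).
#' @return a \code{parametric_surface} of kind \code{"coons"}.
#' @export
coons_patch <- function(boundary, tol = 1e-6) {
  if (length(boundary) != 4L) stop("boundary must hold exactly 4 curves")
  fns <- lapply(boundary, curve_as_function)
  ends <- lapply(fns, function(f) list(a = f(0), b = f(1)))
  for (k in 1:4) {
    nxt <- if (k == 4L) 1L else k + 1L
    gap <- sqrt(sum((ends[[k]]$b - ends[[nxt]]$a)^2))
    if (gap > tol) {
      stop(sprintf("boundary loop not closed: curve %d ends %.3g mm from curve %d start",
                   k, gap, nxt))
    }
  }
  # loop order -> oriented edges of the unit square
  cb <- fns[[1]]                                  # v = 0, u increasing
  cr <- fns[[2]]                                  # u = 1, v increasing
  ct <- function(t) fns[[3]](1 - t)               # v = 1, u increasing
  cl <- function(t) fns[[4]](1 - t)               # u = 0, v increasing
  P00 <- cb(0); P10 <- cb(1); P11 <- cr(1); P01 <- cl(1)
  eval_fn <- function(u, v) {
    n <- length(u)
    out <- matrix(0, n, 3L)
    Cb <- t(vapply(u, cb, numeric(3)))
    Ct <- t(vapply(u, ct, numeric(3)))
    Cl <- t(vapply(v, cl, numeric(3)))
    Cr <- t(vapply(v, cr, numeric(3)))
    for (k in 1:3) {
      out[, k] <- (1 - v) * Cb[, k] + v * Ct[, k] +
        (1 - u) * Cl[, k] + u * Cr[, k] -
        ((1 - u) * (1 - v) * P00[k] + u * (1 - v) * P10[k] +
           (1 - u) * v * P01[k] + u * v * P11[k])
    }
    out
  }
  new_surface("coons", eval_fn, list(boundary = boundary), closed_u = FALSE)
}

curve_as_function <- function(crv) {
  if (inherits(crv, "bspline_curve")) {
    function(t) evaluate_curve(crv, t)[1, ]
  } else if (is.function(crv)) {
    crv
  } else stop("boundary entries must be bspline_curve objects or functions")
}

#' Surface of revolution
#'
#' Revolves a profile curve about an axis. The profile must lie in (or is
#' interpreted in) the half-plane through the axis: in the default frame the
#' axis is z and the profile's x-coordinate is the radius. u is the rotation
#' fraction (full turn over \[0,1\]), v the profile parameter.
#'
#' @param profile an open \code{bspline_curve}; x = radius (>= 0), z =
#'   height. Radii may reach zero at the ends (closed apex) but must not
#'   cross the axis.
#' @param axis list with \code{point} and \code{direction} defining the
#'   rotation axis; default the z-axis through the origin.
#' @return a \code{parametric_surface} of kind \code{"revolution"}, closed
#'   in u.
#' @export
revolve_profile <- function(profile,
                            axis = list(point = c(0, 0, 0),
                                        direction = c(0, 0, 1))) {
  stopifnot(inherits(profile, "bspline_curve"))
  samp <- sample_curve(profile, 256L)
  if (any(samp[, 1] < -1e-9)) {
    stop("profile crosses the rotation axis (negative radius)")
  }
  dir <- axis$direction / sqrt(sum(axis$direction^2))
  # orthonormal frame (e1, e2, dir)
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  eval_fn <- function(u, v) {
    p <- evaluate_curve(profile, v)      # x = radius, z = height
    r <- p[, 1]; h <- p[, 3]
    ang <- 2 * pi * u
    radial <- outer(cos(ang), e1) * r + outer(sin(ang), e2) * r
    sweep(radial + outer(h, dir), 2, axis$point, "+")
  }
  # note: e2 computed as dir x e1 so (e1, e2, dir) is right-handed
  new_surface("revolution", eval_fn,
              list(profile = profile, axis = axis), closed_u = TRUE)
}

#' Tessellate a parametric surface into a triangle mesh
#'
#' Vertices are exact surface evaluations on an nu x nv parameter grid.
#' Surfaces closed in u are seam-welded; grid rows that collapse to a point
#' (poles, tips) are welded to a single vertex so that closed surfaces come
#' out watertight.
#'
#' @param surface a \code{parametric_surface}
#' @param nu,nv grid resolution (>= 3) around and along the surface.
#' @return a \code{triangle_mesh}
#' @export
tessellate <- function(surface, nu = 64L, nv = 48L) {
  nu <- as.integer(nu); nv <- as.integer(nv)
  if (nu < 3L || nv < 3L) stop("nu and nv must be >= 3")
  us <- if (surface$closed_u) (seq_len(nu) - 1L) / nu
  else seq(0, 1, length.out = nu)
  vs <- seq(0, 1, length.out = nv)
  g <- expand.grid(u = us, v = vs)
  P <- eval_surface(surface, g$u, g$v)
  grid <- array(P, dim = c(nu, nv, 3L))
  # collapse degenerate rows (all u at a v-level coincide -> pole)
  m <- mesh_from_grid(grid, wrap_u = surface$closed_u)
  m
}
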