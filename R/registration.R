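#' Rigid transforms
#'
#' A proper rigid motion: \code{p -> rotation \%*\% p + translation}.
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1)
#' @param translation length-3 vector (mm)
#' @return a \code{rigid_transform}
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: angle %.4f rad, translation (%.3f, %.3f, %.3f) mm>\n",
              rotation_angle(x$rotation), x$translation[1], x$translation[2],
              x$translation[3]))
  invisible(x)
}

#' Compose and invert rigid transforms
#' @param a,b \code{rigid_transform}s; the composition applies \code{b}
#'   first, then \code{a}.
#' @return a \code{rigid_transform}
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' @param x a \code{rigid_transform}
#' @rdname compose_transforms
#' @export
invert_transform <- function(x) {
  rigid_transform(t(x$rotation), -as.vector(t(x$rotation) %*% x$translation))
}

#' Rotation angle of a rotation matrix (radians)
#' @param R 3 x 3 rotation matrix
#' @return angle in \[0, pi\]
#' @export
rotation_angle <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
}

#' Apply a rigid transform to points
#' @param transform a \code{rigid_transform}
#' @param points n x 3 matrix
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(transform, points) {
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

# Kabsch/Umeyama: rigid motion mapping X onto Y in least squares
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, translation = cy - as.vector(R %*% cx))
}

#' Best-fit rigid superimposition (iterative closest point)
#'
#' Aligns the moving mesh onto the fixed mesh with point-to-surface ICP:
#' each iteration matches a deterministic subsample of moving vertices to
#' their closest points on the fixed surface, solves the optimal rigid
#' motion in closed form (SVD), and repeats until the correspondence RMS
#' stops improving. Initialisation pre-aligns centroids and principal
#' axes (choosing the axis-sign combination with the smallest initial
#' error, so near-identity poses are never flipped).
#'
#' @param moving,fixed \code{triangle_mesh} objects
#' @param config list overriding any of: \code{max_iterations} (200),
#'   \code{tol} (1e-6 mm change in RMS), \code{n_sample} (1000 moving
#'   vertices), \code{trim} (fraction of worst correspondences discarded,
#'   0), \code{init} ("principal", "centroid" or "identity").
#' @return list with \code{transform} (a \code{rigid_transform} mapping
#'   moving onto fixed), \code{rms} (mm), \code{iterations} and
#'   \code{rms_history}.
#' @export
best_fit_align <- function(moving, fixed, config = list()) {
  cfg <- merge_config(list(max_iterations = 200L, tol = 1e-6,
                                n_sample = 1000L, trim = 0,
                                init = "principal"), config)
  X0 <- moving$vertices[subsample_idx(nrow(moving$vertices), cfg$n_sample), ,
                        drop = FALSE]
  if (nrow(X0) < 3L) stop("degenerate geometry: too few points to align")
  sv <- svd(stats::cov(X0))$d
  if (sv[2] < 1e-12 * max(sv[1], 1)) {
    stop("degenerate geometry: moving points are collinear")
  }
  Tcur <- icp_init(X0, fixed, cfg$init)
  rms_history <- numeric(0)
  rms_prev <- Inf
  for (it in seq_len(cfg$max_iterations)) {
    X <- apply_transform(Tcur, X0)
    cp <- cpp_closest_on_mesh(X, fixed$vertices, fixed$faces)
    keep <- seq_len(nrow(X))
    if (cfg$trim > 0) {
      keep <- order(cp$dist)[seq_len(max(3L, floor((1 - cfg$trim) * nrow(X))))]
    }
    rms <- sqrt(mean(cp$dist[keep]^2))
    rms_history <- c(rms_history, rms)
    if (abs(rms_prev - rms) < cfg$tol) break
    rms_prev <- rms
    fit <- kabsch(X0[keep, , drop = FALSE], cp$points[keep, , drop = FALSE])
    Tcur <- rigid_transform(fit$rotation, fit$translation)
  }
  list(transform = Tcur, rms = rms_history[length(rms_history)],
       iterations = length(rms_history), rms_history = rms_history)
}

icp_init <- function(X0, fixed, init) {
  cx <- colMeans(X0)
  Yv <- fixed$vertices
  cy <- colMeans(Yv)
  if (init == "identity") return(rigid_transform())
  if (init == "centroid") return(rigid_transform(diag(3), cy - cx))
  # principal axes with sign disambiguation by initial fit quality
  Ex <- eigen(stats::cov(X0), symmetric = TRUE)$vectors
  Ey <- eigen(stats::cov(Yv), symmetric = TRUE)$vectors
  cand <- list(rigid_transform(diag(3), cy - cx))  # centroid-only fallback
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    S <- diag(c(s1, s2, 1))
    R <- Ey %*% S %*% t(Ex)
    if (det(R) < 0) R <- Ey %*% diag(c(s1, s2, -1)) %*% t(Ex)
    cand[[length(cand) + 1L]] <- rigid_transform(R, cy - as.vector(R %*% cx))
  }
  probe <- X0[subsample_idx(nrow(X0), 200L), , drop = FALSE]
  errs <- vapply(cand, function(tr) {
    d <- cpp_closest_on_mesh(apply_transform(tr, probe), Yv, fixed$faces)$dist
    mean(d^2)
  }, numeric(1))
  cand[[which.min(errs)]]
}

#' Signed surface deviation map
#'
#' For every vertex of the (pre-aligned) parametric mesh: the distance to
#' the nearest point of the segmented surface, signed positive where the
#' parametric vertex lies outside the closed segmented mesh (parametric
#' excess, rendered in warm colours) and negative where it lies inside
#' (parametric lack, cold colours).
#'
#' @param parametric a \code{triangle_mesh}, already aligned to
#'   \code{segmented} (see \code{\link{best_fit_align}})
#' @param segmented a closed \code{triangle_mesh}
#' @return a \code{distance_map}: numeric vector of signed distances (mm),
#'   one per parametric vertex.
#' @export
signed_distance_map <- function(parametric, segmented) {
  if (!mesh_is_closed(segmented)) {
    stop("segmented mesh must be closed: the deviation sign is undefined otherwise")
  }
  cp <- cpp_closest_on_mesh(parametric$vertices, segmented$vertices,
                            segmented$faces)
  inside <- cpp_points_inside(parametric$vertices, segmented$vertices,
                              segmented$faces)
  d <- cp$dist * ifelse(inside, -1, 1)
  structure(d, class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("<distance_map: %d vertices, mean |d| %.3f mm, range [%.3f, %.3f] mm>\n",
              length(v), mean(abs(v)), min(v), max(v)))
  invisible(x)
}

#' Per-region deviation report
#'
#' Splits the parametric mesh vertices into anatomical z-bands — apex band
#' (apical fraction of the axial extent), CEJ band (fixed-width band
#' around the cervical plane), crown (above the CEJ band) and root body
#' (the remainder) — and summarises the signed deviation map per region
#' and overall.
#'
#' @param dmap a \code{distance_map} from \code{\link{signed_distance_map}}
#' @param mesh the parametric \code{triangle_mesh} the map lives on
#' @param region_config list overriding \code{apex_frac} (0.15),
#'   \code{cej_halfwidth} (1 mm) and \code{cej_z} (cervical plane height;
#'   estimated from the width profile when NULL)
#' @return a \code{deviation_report}: data.frame of region statistics plus
#'   overall summary attributes.
#' @export
deviation_report <- function(dmap, mesh, region_config = list()) {
  cfg <- merge_config(list(apex_frac = 0.15, cej_halfwidth = 1,
                                cej_z = NULL), region_config)
  d <- as.numeric(dmap)
  stopifnot(length(d) == nrow(mesh$vertices))
  z <- mesh$vertices[, 3]
  if (is.null(cfg$cej_z)) {
    bb <- range(z)
    zl <- seq(bb[1] + 1e-3, bb[2] - 1e-3, length.out = 120L)
    w <- slice_widths(mesh, zl)
    cfg$cej_z <- locate_waist(mesh, zl, w, which.max(w))$z
  }
  apex_top <- min(z) + cfg$apex_frac * (max(z) - min(z))
  region <- ifelse(z <= apex_top, "apex",
                   ifelse(abs(z - cfg$cej_z) <= cfg$cej_halfwidth, "cej",
                          ifelse(z > cfg$cej_z + cfg$cej_halfwidth,
                                 "crown", "root")))
  regions <- c("apex", "root", "cej", "crown")
  rows <- lapply(regions, function(rg) {
    sel <- region == rg
    if (!any(sel)) {
      return(data.frame(region = rg, n = 0L, mean_abs = NA_real_,
                        max_abs = NA_real_, min_signed = NA_real_,
                        max_signed = NA_real_))
    }
    data.frame(region = rg, n = sum(sel), mean_abs = mean(abs(d[sel])),
               max_abs = max(abs(d[sel])), min_signed = min(d[sel]),
               max_signed = max(d[sel]))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("deviation_report", "data.frame"),
            overall_mean_abs = mean(abs(d)), overall_max_abs = max(abs(d)),
            overall_min_signed = min(d), overall_max_signed = max(d),
            cej_z = cfg$cej_z)
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("<deviation_report: overall mean |d| %.3f mm, max |d| %.3f mm, signed [%.3f, %.3f] mm>\n",
              attr(x, "overall_mean_abs"), attr(x, "overall_max_abs"),
              attr(x, "overall_min_signed"), attr(x, "overall_max_signed")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
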