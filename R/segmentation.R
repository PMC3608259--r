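#' Extract an iso-surface from a scalar volume
#'
#' Computes the level set \code{value == tau} as a triangle mesh in world
#' (mm) coordinates, by marching tetrahedra over the Kuhn six-tetrahedron
#' decomposition of each grid cell with linear interpolation along cell
#' edges. The decomposition is consistent across neighbouring cells and
#' iso-vertices are shared through edge keys, so the extracted surface is
#' watertight whenever the level set closes inside the grid.
#'
#' @param volume a \code{scalar_volume}
#' @param tau iso-level, strictly between the volume minimum and maximum
#' @return a \code{triangle_mesh}
#' @export
extract_isosurface <- function(volume, tau) {
  stopifnot(inherits(volume, "scalar_volume"))
  rng <- range(volume$values)
  if (!is.finite(tau) || tau <= rng[1] || tau >= rng[2]) {
    stop(sprintf("tau = %g outside the open data range (%g, %g): empty level set",
                 tau, rng[1], rng[2]))
  }
  res <- cpp_isosurface(as.vector(volume$values), dim(volume$values),
                        volume$origin, volume$spacing, tau)
  if (nrow(res$vertices) == 0L) stop("empty level set at tau = ", tau)
  triangle_mesh(res$vertices, res$faces)
}

#' Calibrate the segmentation threshold by superimposition
#'
#' Emulates reference-model-guided threshold selection: for every
#' candidate threshold the iso-surface is extracted, rigidly best-fit
#' aligned to the reference surface, and scored by the mean absolute
#' distance from its vertices to the reference; the calibrated threshold
#' minimises that superimposition error. The alignment step absorbs any
#' rigid misplacement of the reference, so the objective depends only on
#' shape.
#'
#' @param volume a \code{scalar_volume} (e.g. CBCT-like occupancy)
#' @param reference a closed \code{triangle_mesh} (e.g. an optical scan)
#' @param tau_grid candidate thresholds, all strictly inside the data range
#' @param align_config configuration list passed to
#'   \code{\link{best_fit_align}}
#' @param n_sample number of iso-surface vertices scored per threshold
#'   (deterministic subsample)
#' @return a \code{threshold_calibration}: \code{tau_star} and the
#'   \code{objective_curve} data.frame of (tau, mean_abs_distance).
#' @export
calibrate_threshold <- function(volume, reference, tau_grid,
                                align_config = list(), n_sample = 1500L) {
  stopifnot(inherits(volume, "scalar_volume"),
            inherits(reference, "triangle_mesh"))
  if (!mesh_is_closed(reference)) stop("reference mesh must be closed")
  rng <- range(volume$values)
  if (any(tau_grid <= rng[1] | tau_grid >= rng[2])) {
    stop("tau_grid values must lie strictly inside the data range")
  }
  obj <- rep(NA_real_, length(tau_grid))
  for (i in seq_along(tau_grid)) {
    surf <- tryCatch(extract_isosurface(volume, tau_grid[i]),
                     error = function(e) NULL)
    if (is.null(surf)) next
    acfg <- merge_config(list(tol = 1e-5, max_iterations = 80L,
                                   n_sample = 600L), align_config)
    fit <- best_fit_align(surf, reference, config = acfg)
    moved <- transform_mesh(surf, fit$transform$rotation,
                            fit$transform$translation)
    idx <- subsample_idx(nrow(moved$vertices), n_sample)
    d <- cpp_closest_on_mesh(moved$vertices[idx, , drop = FALSE],
                             reference$vertices, reference$faces)$dist
    obj[i] <- mean(d)
  }
  if (all(is.na(obj))) stop("iso-surface extraction failed for every tau")
  tau_star <- tau_grid[which.min(obj)]
  structure(list(tau_star = tau_star,
                 objective_curve = data.frame(tau = tau_grid,
                                              mean_abs_distance = obj)),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("<threshold_calibration: tau* = %g>\n", x$tau_star))
  print(x$objective_curve, row.names = FALSE)
  invisible(x)
}

# evenly spaced deterministic subsample of 1..n
subsample_idx <- function(n, k) {
  if (n <= k) seq_len(n) else unique(round(seq(1L, n, length.out = k)))
}
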