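#' Triangle meshes
#'
#' A minimal triangle-mesh container: an N x 3 matrix of vertex coordinates
#' (mm) and an M x 3 integer matrix of 1-based vertex indices per face. This
#' is the discrete carrier for all tessellated parametric surfaces and all
#' segmented models in the package.
#'
#' @param vertices numeric N x 3 matrix (mm).
#' @param faces integer M x 3 matrix of vertex indices (1-based).
#' @param validate check index bounds and reject NA/non-finite input?
#' @return an object of class \code{triangle_mesh}.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as_points3(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (validate) {
    if (nrow(faces) > 0L &&
        (min(faces) < 1L || max(faces) > nrow(vertices))) {
      stop("face indices out of range")
    }
  }
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("<triangle_mesh: %d vertices, %d faces, %s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (mesh_is_closed(x)) "closed" else "open"))
  cat(sprintf("  bbox x [%.2f, %.2f] y [%.2f, %.2f] z [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# undirected edge table: one row per face edge, key = "lo.hi"
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Is a mesh closed (watertight)?
#'
#' A mesh is closed when every undirected edge is shared by exactly two
#' faces. Closedness is required wherever an inside/outside decision is
#' made (signed deviation maps, voxelisation).
#'
#' @param mesh a \code{triangle_mesh}.
#' @return logical.
#' @export
mesh_is_closed <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  e <- mesh_edges(mesh)
  key <- e[, 1] * (nrow(mesh$vertices) + 1) + e[, 2]
  all(tabulate(match(key, unique(key))) == 2L)
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Face areas and total surface area
#' @param mesh a \code{triangle_mesh}
#' @return \code{face_areas}: numeric vector (mm^2); \code{mesh_area}: total.
#' @export
face_areas <- function(mesh) {
  0.5 * sqrt(rowSums(face_cross(mesh)^2))
}

#' @rdname face_areas
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Merge coincident vertices and drop degenerate faces
#'
#' Vertices closer than \code{tol} are merged; faces whose area falls below
#' \code{area_tol} afterwards (slivers, collapsed grid cells, pole caps) are
#' removed. Used when assembling tooth meshes from multiple surface patches
#' that share boundary curves.
#'
#' @param mesh a \code{triangle_mesh}
#' @param tol merge distance (mm)
#' @param area_tol minimum retained face area (mm^2)
#' @return a cleaned \code{triangle_mesh}
#' @export
weld_mesh <- function(mesh, tol = 1e-7, area_tol = 1e-10) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  idx <- match(key, key)            # first occurrence representative
  keep <- which(idx == seq_along(idx))
  remap <- match(idx, keep)
  v2 <- v[keep, , drop = FALSE]
  f2 <- matrix(remap[mesh$faces], ncol = 3L)
  # drop combinatorially degenerate faces
  ok <- f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
  f2 <- f2[ok, , drop = FALSE]
  m <- triangle_mesh(v2, f2)
  a <- face_areas(m)
  m$faces <- m$faces[a > area_tol, , drop = FALSE]
  drop_unused_vertices(m)
}

drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[mesh$faces], ncol = 3L))
}

#' Apply a rigid (or affine) transform to a mesh
#' @param mesh a \code{triangle_mesh}
#' @param rotation 3 x 3 matrix (applied on the left)
#' @param translation length-3 vector (mm)
#' @return the transformed mesh
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  triangle_mesh(v, mesh$faces, validate = FALSE)
}

#' Uniformly scale a mesh about a point
#' @param mesh a \code{triangle_mesh}
#' @param s scale factor
#' @param center point to scale about (default origin)
#' @return the scaled mesh
#' @export
scale_mesh <- function(mesh, s, center = c(0, 0, 0)) {
  v <- sweep(mesh$vertices, 2, center, "-") * s
  triangle_mesh(sweep(v, 2, center, "+"), mesh$faces, validate = FALSE)
}

# --- ring-stack construction -------------------------------------------------
# Build a tube mesh from a list of rings (each an nu x 3 matrix, consistently
# oriented, wrap-around in u). Ends may be left open, pole-welded to a point,
# or fan-capped to the ring centroid.
mesh_from_rings <- function(rings, bottom = c("none", "pole", "fan"),
                            top = c("none", "pole", "fan"),
                            bottom_point = NULL, top_point = NULL) {
  bottom <- match.arg(bottom)
  top <- match.arg(top)
  nu <- nrow(rings[[1]])
  nv <- length(rings)
  stopifnot(nv >= 2L, all(vapply(rings, nrow, 1L) == nu))
  V <- do.call(rbind, rings)
  F_ <- vector("list", nv - 1L)
  for (j in seq_len(nv - 1L)) {
    i0 <- (j - 1L) * nu + seq_len(nu)
    i1 <- j * nu + seq_len(nu)
    nx <- c(seq_len(nu)[-1], 1L)
    F_[[j]] <- rbind(cbind(i0, i1, i1[nx]), cbind(i0, i1[nx], i0[nx]))
  }
  F_ <- do.call(rbind, F_)
  close_end <- function(kind, ring_idx, point, flip) {
    if (kind == "none") return(NULL)
    pt <- if (!is.null(point)) point else colMeans(V[ring_idx, , drop = FALSE])
    V <<- rbind(V, matrix(pt, 1L, 3L))
    pi_ <- nrow(V)
    nx <- c(ring_idx[-1], ring_idx[1])
    tri <- cbind(ring_idx, nx, pi_)
    if (flip) tri <- tri[, c(2, 1, 3)]
    tri
  }
  fb <- close_end(bottom, seq_len(nu), bottom_point, flip = FALSE)
  ft <- close_end(top, (nv - 1L) * nu + seq_len(nu), top_point, flip = TRUE)
  m <- triangle_mesh(V, rbind(F_, fb, ft))
  weld_mesh(m)
}

# Grid-based mesh (open in u unless wrap_u), used for Coons patches.
# grid is an array dim c(nu, nv, 3).
mesh_from_grid <- function(grid, wrap_u = FALSE) {
  nu <- dim(grid)[1]; nv <- dim(grid)[2]
  V <- matrix(grid, nu * nv, 3L)
  idx <- function(i, j) (j - 1L) * nu + i
  iu <- seq_len(if (wrap_u) nu else nu - 1L)
  iu_next <- if (wrap_u) c(seq_len(nu)[-1], 1L)[iu] else iu + 1L
  F_ <- vector("list", nv - 1L)
  for (j in seq_len(nv - 1L)) {
    a <- idx(iu, j); b <- idx(iu_next, j)
    c_ <- idx(iu_next, j + 1L); d <- idx(iu, j + 1L)
    F_[[j]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  }
  weld_mesh(triangle_mesh(V, do.call(rbind, F_)))
}

#' Combine meshes sharing boundary curves into one
#' @param ... \code{triangle_mesh} objects
#' @param tol vertex merge tolerance (mm)
#' @return a single welded \code{triangle_mesh}
#' @export
merge_meshes <- function(..., tol = 1e-7) {
  ms <- list(...)
  off <- 0L
  V <- list(); F_ <- list()
  for (m in ms) {
    V[[length(V) + 1L]] <- m$vertices
    F_[[length(F_) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  weld_mesh(triangle_mesh(do.call(rbind, V), do.call(rbind, F_)), tol = tol)
}

# --- planar slicing ----------------------------------------------------------
# Intersection of mesh edges with the plane z = z0. Returns the crossing
# points and, if contours = TRUE, a contour id per crossing (connected
# components of the slice polyline, linked through shared faces).
mesh_slice <- function(mesh, z0, contours = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  z <- v[, 3]
  below <- z < z0
  n_below <- below[f[, 1]] + below[f[, 2]] + below[f[, 3]]
  cross_f <- which(n_below == 1L | n_below == 2L)
  if (length(cross_f) == 0L) {
    return(list(points = matrix(numeric(0), 0, 3), contour = integer(0),
                n_contours = 0L))
  }
  # per crossing face, its two crossing edges
  fe <- f[cross_f, , drop = FALSE]
  epairs <- rbind(fe[, c(1, 2)], fe[, c(2, 3)], fe[, c(3, 1)])
  face_of <- rep(seq_along(cross_f), 3L)
  s1 <- z[epairs[, 1]] - z0
  s2 <- z[epairs[, 2]] - z0
  hit <- s1 * s2 < 0
  epairs <- epairs[hit, , drop = FALSE]
  face_of <- face_of[hit]
  tt <- (z0 - z[epairs[, 1]]) / (z[epairs[, 2]] - z[epairs[, 1]])
  pts <- v[epairs[, 1], , drop = FALSE] +
    tt * (v[epairs[, 2], , drop = FALSE] - v[epairs[, 1], , drop = FALSE])
  if (!contours) {
    return(list(points = pts, contour = NULL, n_contours = NA_integer_))
  }
  # connected components: crossing edges are nodes, faces connect their pair
  ekey <- paste(pmin(epairs[, 1], epairs[, 2]),
                pmax(epairs[, 1], epairs[, 2]))
  eid <- match(ekey, unique(ekey))
  n_nodes <- max(eid)
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (ff in unique(face_of)) {
    nodes <- unique(eid[face_of == ff])
    if (length(nodes) == 2L) {
      a <- find(nodes[1]); b <- find(nodes[2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(eid, find, 1L)
  comp <- match(roots, unique(roots))
  list(points = pts, contour = comp, n_contours = max(comp))
}

# Mesio-distal (x axis) slice width at each z level; NA when the plane
# misses the mesh.
slice_widths <- function(mesh, zlevels) {
  vapply(zlevels, function(z0) {
    s <- mesh_slice(mesh, z0)
    if (nrow(s$points) == 0L) return(NA_real_)
    max(s$points[, 1]) - min(s$points[, 1])
  }, numeric(1))
}

#' Axis-aligned bounding box
#' @param mesh a \code{triangle_mesh}
#' @return 2 x 3 matrix (min row, max row), mm
#' @export
mesh_bbox <- function(mesh) {
  unname(apply(mesh$vertices, 2, range))
}

# shallow config merge: list-valued options (rosters, noise models,
# nested configs) replace the default wholesale rather than being merged
# field-by-field as utils::modifyList would do
merge_config <- function(defaults, config) {
  for (nm in names(config)) defaults[[nm]] <- config[[nm]]
  defaults
}
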