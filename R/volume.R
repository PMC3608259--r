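#' Scalar volumes on axis-aligned grids
#'
#' A simple voxel container standing in for CBCT-derived data: a 3D array
#' of values with uniform per-axis spacing (mm/voxel) and the world
#' coordinate of the first voxel centre.
#'
#' @param values 3D numeric array
#' @param spacing length-3 positive vector, mm per voxel along x, y, z
#' @param origin length-3 vector: world position (mm) of voxel (1,1,1)
#' @return a \code{scalar_volume}
#' @export
scalar_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (any(dim(values) < 2L)) stop("grid must have at least 2 voxels per axis")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive numbers")
  }
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume: %s voxels, spacing %s mm, range [%.3g, %.3g]>\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxelise a closed mesh into a binary occupancy volume
#'
#' Voxel centres inside the mesh get value 1, outside 0 (parity of ray
#' crossings along grid columns). The grid is derived from the mesh
#' bounding box plus a margin.
#'
#' @param mesh a closed \code{triangle_mesh}
#' @param spacing voxel size in mm (scalar or length 3)
#' @param margin empty border around the mesh, mm
#' @return a \code{scalar_volume} of 0/1 occupancy
#' @export
voxelize_mesh <- function(mesh, spacing = 0.4, margin = 2) {
  if (!mesh_is_closed(mesh)) stop("mesh must be closed to voxelise")
  spacing <- rep_len(as.numeric(spacing), 3L)
  bb <- mesh_bbox(mesh)
  origin <- bb[1, ] - margin
  dims <- as.integer(ceiling((bb[2, ] - bb[1, ] + 2 * margin) / spacing)) + 1L
  occ <- cpp_voxelize(mesh$vertices, mesh$faces, dims, origin, spacing)
  scalar_volume(array(occ, dim = dims), spacing = spacing, origin = origin)
}

#' Gaussian blur of a scalar volume
#'
#' Separable Gaussian smoothing (FFT-based circular convolution; the
#' volume should carry an empty border, as \code{voxelize_mesh} provides).
#' Used to emulate the partial-volume blur of CBCT reconstructions around
#' a binary segmentation.
#'
#' @param volume a \code{scalar_volume}
#' @param sigma standard deviation in voxels
#' @return the blurred \code{scalar_volume}
#' @export
blur_volume <- function(volume, sigma = 1) {
  a <- volume$values
  d <- dim(a)
  kern1 <- function(n) {
    i <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-i^2 / (2 * sigma^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(d[1]), kern1(d[2])), kern1(d[3]))
  dim(K) <- d
  out <- Re(stats::fft(stats::fft(a) * stats::fft(K), inverse = TRUE)) / prod(d)
  volume$values <- out
  volume
}

#' Read and write NRRD volumes
#'
#' Minimal NRRD support sufficient for desk-scale scalar volumes: 3D,
#' double or float, raw little-endian or ascii encoding, uniform spacings.
#'
#' @param volume a \code{scalar_volume}
#' @param path file path (.nrrd)
#' @param encoding \code{"raw"} (binary little-endian) or \code{"ascii"}
#' @return \code{read_nrrd} returns a \code{scalar_volume};
#'   \code{write_nrrd} returns \code{path} invisibly.
#' @export
write_nrrd <- function(volume, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  d <- dim(volume$values)
  hdr <- c("NRRD0004",
           "# toothrecon scalar volume",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.9g %.9g %.9g", volume$spacing[1],
                   volume$spacing[2], volume$spacing[3]),
           sprintf("axis mins: %.9g %.9g %.9g", volume$origin[1],
                   volume$origin[2], volume$origin[3]),
           "endian: little",
           sprintf("encoding: %s", encoding),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.vector(volume$values), con, size = 8L, endian = "little")
  } else {
    writeLines(paste(format(as.vector(volume$values), digits = 12),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || ln == "") break
    hdr <- c(hdr, ln)
  }
  field <- function(name, default = NULL) {
    hit <- grep(paste0("^", name, ": "), hdr, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^", name, ": "), "", hit[1])
  }
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file: ", path)
  sizes <- as.integer(strsplit(field("sizes"), " +")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  spacing <- as.numeric(strsplit(field("spacings", "1 1 1"), " +")[[1]])
  origin <- as.numeric(strsplit(field("axis mins", "0 0 0"), " +")[[1]])
  enc <- field("encoding", "raw")
  type <- field("type", "double")
  n <- prod(sizes)
  vals <- if (enc == "raw") {
    size <- if (type %in% c("double", "float64")) 8L
    else if (type %in% c("float", "float32")) 4L
    else stop("unsupported NRRD type: ", type)
    readBin(con, "numeric", n = n, size = size, endian = "little")
  } else if (enc %in% c("ascii", "txt", "text")) {
    scan(con, what = double(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc)
  scalar_volume(array(vals, dim = sizes), spacing = spacing, origin = origin)
}

# voxel-centre world coordinates along one axis
volume_axis <- function(volume, k) {
  volume$origin[k] + (seq_len(dim(volume$values)[k]) - 1L) * volume$spacing[k]
}
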