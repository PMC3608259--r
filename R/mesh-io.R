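#' Read and write triangle meshes (STL, PLY)
#'
#' STL is written binary little-endian (units mm) and read in both binary
#' and ascii dialects; since STL stores no connectivity, reading welds
#' coincident corners back into shared vertices. PLY is written ascii,
#' optionally carrying a per-vertex scalar attribute (e.g. a signed
#' deviation map) as property \code{signed_distance}.
#'
#' @param mesh a \code{triangle_mesh}
#' @param path file path
#' @return readers return a \code{triangle_mesh}; writers return
#'   \code{path} invisibly.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "toothrecon binary STL (mm)"))
  writeBin(hdr[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- face_cross(mesh)
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  # 12 floats + attribute count per facet
  block <- matrix(0, nrow = 12L, ncol = nf)
  block[1:3, ] <- t(nrm)
  block[4:6, ] <- t(v[f[, 1], , drop = FALSE])
  block[7:9, ] <- t(v[f[, 2], , drop = FALSE])
  block[10:12, ] <- t(v[f[, 3], , drop = FALSE])
  raw_f <- writeBin(as.vector(block), raw(), size = 4L, endian = "little")
  dim(raw_f) <- c(48L, nf)
  zero2 <- as.raw(c(0, 0))
  out <- rbind(raw_f, matrix(rep(zero2, nf), nrow = 2L))
  writeBin(as.vector(out), con)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = 80L)
  close(con)
  if (grepl("^solid", rawToChar(head[1:5]))) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    if (nrow(nums) %% 3L != 0L) stop("malformed ascii STL: ", path)
    V <- nums
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    raw_all <- readBin(con, "raw", n = 50L * nf)
    dim(raw_all) <- c(50L, nf)
    fl <- readBin(as.vector(raw_all[1:48, ]), "numeric", n = 12L * nf,
                  size = 4L, endian = "little")
    dim(fl) <- c(12L, nf)
    V <- matrix(as.vector(fl[4:12, ]), ncol = 3L, byrow = TRUE)
  }
  F_ <- matrix(seq_len(nrow(V)), ncol = 3L, byrow = TRUE)
  weld_mesh(triangle_mesh(V, F_), tol = 1e-5)
}

#' @param scalar optional per-vertex numeric attribute written as property
#'   \code{signed_distance}
#' @rdname write_stl
#' @export
write_ply <- function(mesh, path, scalar = NULL) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  if (!is.null(scalar) && length(scalar) != nv) {
    stop("scalar attribute must have one value per vertex")
  }
  hdr <- c("ply", "format ascii 1.0", "comment toothrecon (mm)",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           if (!is.null(scalar)) "property float signed_distance",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  vb <- if (is.null(scalar)) mesh$vertices else cbind(mesh$vertices, scalar)
  vlines <- apply(format(vb, digits = 9, trim = TRUE, scientific = FALSE),
                  1L, paste, collapse = " ")
  flines <- paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  end <- which(txt == "end_header")[1]
  if (is.na(end)) stop("not an ascii PLY file: ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", txt, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", txt, value = TRUE)[1]))
  vparts <- strsplit(trimws(txt[end + seq_len(nv)]), "\\s+")
  V <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
  fparts <- strsplit(trimws(txt[end + nv + seq_len(nf)]), "\\s+")
  F_ <- do.call(rbind, lapply(fparts, function(p) as.integer(p[2:4]) + 1L))
  triangle_mesh(V, F_)
}

# dispatch on file extension (used by the command-line interface)
read_mesh <- function(path) {
  switch(tolower(tools::file_ext(path)),
         stl = read_stl(path),
         ply = read_ply(path),
         stop("unsupported mesh format: ", path))
}

write_mesh <- function(mesh, path, scalar = NULL) {
  switch(tolower(tools::file_ext(path)),
         stl = write_stl(mesh, path),
         ply = write_ply(mesh, path, scalar = scalar),
         stop("unsupported mesh format: ", path))
}
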