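#' Measure the anatomical control parameters from a tooth mesh
#'
#' Recovers the named measurements from a closed mesh in the canonical
#' frame (+z occlusal, +x mesial): widths are mesio-distal (x) extents of
#' horizontal cross sections, matching what a panoramic projection can
#' measure; heights are axial extents. The equator EQU is the widest crown
#' slice; the cement-enamel junction is located as the cervical waist (the
#' first local width minimum walking down from the equator plane, with a
#' narrowest-middle-third fallback for waistless shapes such as cylinders);
#' root widths are taken at half root length; for multi-rooted teeth the
#' furcation is the highest plane at which the cross section splits into
#' two or more contours, refined by bisection.
#'
#' @param mesh a closed \code{triangle_mesh} in the canonical frame
#' @param tooth_class \code{"incisor"} or \code{"molar"}
#' @param n_slices number of z levels for the width profile
#' @return a \code{tooth_measures} object (method \code{"mesh"})
#' @export
measure_mesh <- function(mesh, tooth_class = c("incisor", "molar"),
                         n_slices = 200L) {
  tooth_class <- match.arg(tooth_class)
  stopifnot(inherits(mesh, "triangle_mesh"))
  bb <- mesh_bbox(mesh)
  zmin <- bb[1, 3]; zmax <- bb[2, 3]
  ext <- zmax - zmin
  # slight irrational offset keeps slice planes off tessellation rings
  zl <- seq(zmin + 1e-3 * ext, zmax - 1e-3 * ext,
            length.out = n_slices) + ext * 1.137e-5
  w <- slice_widths(mesh, zl)
  i_equ <- which.max(w)
  EQU <- w[i_equ]
  waist <- locate_waist(mesh, zl, w, i_equ)
  z_cej <- waist$z
  CEJ <- waist$width
  if (tooth_class == "incisor") {
    RL <- z_cej - zmin
    RAD <- slice_widths(mesh, zmin + RL / 2 + 1e-4 * ext)
    values <- list(T_H = ext, C_H = zmax - z_cej, CEJ = CEJ,
                   EQU = EQU, RAD = RAD)
    return(tooth_measures(NA_character_, "mesh", values))
  }
  # molar: furcation and per-root measures from slice contours
  furc <- locate_furcation(mesh, zl[zl < z_cej])
  v <- mesh$vertices
  roots <- root_apexes(mesh, zl, furc)
  z_half <- function(apex) apex + (furc - apex) / 2
  root_width <- function(label, apex) {
    s <- mesh_slice(mesh, z_half(apex) + 1e-4 * ext, contours = TRUE)
    labs <- label_contours(s)
    sel <- s$contour %in% which(labs == label)
    if (!any(sel)) return(NA_real_)
    max(s$points[sel, 1]) - min(s$points[sel, 1])
  }
  mes_top <- max(v[v[, 1] > 0, 3])
  dis_top <- max(v[v[, 1] < 0, 3])
  values <- list(
    EQU = EQU, CEJ = CEJ,
    MC_H = mes_top - z_cej, DC_H = dis_top - z_cej,
    MT_H = mes_top - roots[["mesial"]], DT_H = dis_top - roots[["distal"]],
    MRAD = root_width("mesial", roots[["mesial"]]),
    DRAD = root_width("distal", roots[["distal"]]),
    H_FURC = furc - max(roots[["mesial"]], roots[["distal"]])
  )
  if ("palatal" %in% names(roots)) {
    values$PT_H <- zmax - roots[["palatal"]]
    values$PRAD <- root_width("palatal", roots[["palatal"]])
  }
  tooth_measures(NA_character_, "mesh", values)
}

# cervical waist: first local width minimum walking down from the equator
locate_waist <- function(mesh, zl, w, i_equ, tol = 5e-3) {
  z_w <- NULL
  # walk down from the equator: a waist slice is no wider than the slice
  # above it and strictly narrower than the slice below it
  for (j in rev(seq_len(i_equ - 1L))) {
    if (j <= 1L) break
    if (!is.na(w[j]) && !is.na(w[j - 1L]) && !is.na(w[j + 1L]) &&
        w[j] <= w[j + 1L] + tol && w[j] < w[j - 1L] - tol) {
      z_w <- zl[j]
      break
    }
  }
  if (is.null(z_w)) {
    # fallback: narrowest slice within the middle third of the axial extent
    zmin <- min(zl); zmax <- max(zl)
    mid <- zl > zmin + (zmax - zmin) / 3 & zl < zmax - (zmax - zmin) / 3
    j <- which(mid)[which.min(w[mid])]
    z_w <- zl[j]
  }
  # refine on a fine local grid
  dz <- zl[2] - zl[1]
  zf <- seq(z_w - dz, z_w + dz, length.out = 21L)
  wf <- slice_widths(mesh, zf)
  jf <- which.min(wf)
  list(z = zf[jf], width = wf[jf])
}

# highest z at which the cross section has >= 2 contours (bisection-refined)
locate_furcation <- function(mesh, zl_below) {
  nc <- vapply(rev(zl_below), function(z)
    mesh_slice(mesh, z, contours = TRUE)$n_contours, integer(1))
  k <- which(nc >= 2L)[1]
  if (is.na(k)) stop("furcation not found: mesh has a single root")
  zs <- rev(zl_below)
  lo <- zs[k]                      # multi-contour
  hi <- if (k > 1L) zs[k - 1L] else lo + (zs[1] - zs[2])
  for (it in 1:12) {
    mid <- (lo + hi) / 2
    if (mesh_slice(mesh, mid, contours = TRUE)$n_contours >= 2L) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

# label a sliced contour set by centroid direction in the xy plane
label_contours <- function(s) {
  if (is.null(s$contour) || s$n_contours == 0L) return(character(0))
  refs <- rbind(mesial = c(1, 0), distal = c(-1, 0), palatal = c(0, -1))
  vapply(seq_len(s$n_contours), function(ci) {
    cen <- colMeans(s$points[s$contour == ci, 1:2, drop = FALSE])
    cen <- cen / max(sqrt(sum(cen^2)), 1e-9)
    rownames(refs)[which.max(refs %*% cen)]
  }, character(1))
}

# per-root apex z: lowest slice at which a labelled contour appears,
# refined to the lowest mesh vertex near that contour
root_apexes <- function(mesh, zl, furc) {
  zs <- zl[zl < furc]
  found <- list()
  for (z in zs) {                  # ascending z
    s <- mesh_slice(mesh, z, contours = TRUE)
    if (s$n_contours == 0L) next
    labs <- label_contours(s)
    for (ci in seq_along(labs)) {
      lab <- labs[ci]
      if (!is.null(found[[lab]])) next
      cen <- colMeans(s$points[s$contour == ci, 1:2, drop = FALSE])
      v <- mesh$vertices
      near <- abs(v[, 1] - cen[1]) < 2.5 & abs(v[, 2] - cen[2]) < 2.5 &
        v[, 3] < z + 0.5
      found[[lab]] <- if (any(near)) min(v[near, 3]) else z
    }
    if (all(c("mesial", "distal") %in% names(found)) &&
        length(found) >= s$n_contours) break
  }
  if (!all(c("mesial", "distal") %in% names(found))) {
    stop("could not identify mesial and distal root apexes")
  }
  unlist(found)
}

#' Named measurement record for one tooth and one method
#'
#' @param tooth_id FDI tooth number as a string (e.g. "2.1"), or NA
#' @param method one of \code{"in_vivo"}, \code{"PAN"}, \code{"CBCT"},
#'   \code{"mesh"}
#' @param values named list/vector of positive measurements (mm)
#' @return a \code{tooth_measures} object
#' @export
tooth_measures <- function(tooth_id, method, values) {
  method <- match.arg(method, c("in_vivo", "PAN", "CBCT", "mesh"))
  values <- lapply(as.list(values), unname)
  num <- unlist(values)
  if (any(!is.finite(num) | num <= 0)) {
    stop("all measurement values must be positive and finite")
  }
  crown_names <- c("EQU", "CEJ", "C_H", "MC_H", "DC_H")
  if (method == "in_vivo" && !all(names(values) %in% crown_names)) {
    stop("in_vivo records may contain crown measures only")
  }
  structure(list(tooth_id = tooth_id, method = method, values = values),
            class = "tooth_measures")
}

#' @export
print.tooth_measures <- function(x, ...) {
  cat(sprintf("<tooth_measures: tooth %s, method %s>\n", x$tooth_id, x$method))
  print(round(unlist(x$values), 3))
  invisible(x)
}

#' Dahlberg repeatability error
#'
#' The classical estimate of the "true" per-measurement error standard
#' deviation from replicate measurement pairs:
#' \deqn{S_D = \sqrt{ \sum_i d_i^2 / (2n) }}
#' where \eqn{d_i} is the difference within replicate pair i and n the
#' number of pairs.
#'
#' @param pairs an n x 2 matrix/data.frame of replicate measurements, or a
#'   list of length-2 vectors.
#' @return a \code{dahlberg_result} with fields \code{S_D} (mm) and
#'   \code{n}.
#' @examples
#' dahlberg_error(rbind(c(1, 2), c(3, 3)))  # S_D = 0.5
#' @export
dahlberg_error <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) p[1:2]))
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 1L || ncol(pairs) != 2L) {
    stop("pairs must hold at least one replicate pair (two columns)")
  }
  if (anyNA(pairs)) stop("replicate pairs must not contain NA")
  d <- pairs[, 1] - pairs[, 2]
  structure(list(S_D = sqrt(sum(d^2) / (2 * nrow(pairs))), n = nrow(pairs)),
            class = "dahlberg_result")
}

#' @export
print.dahlberg_result <- function(x, ...) {
  cat(sprintf("Dahlberg error S_D = %.4f mm (n = %d replicate pairs)\n",
              x$S_D, x$n))
  invisible(x)
}

#' Multiplicative scale calibration between two measurement series
#'
#' Least-squares fit of the factor s minimising
#' sum (reference_i - s * target_i)^2, used to bring measurements recorded
#' in device units (e.g. CBCT voxel units) onto the millimetre scale of a
#' reference method before any comparison.
#'
#' @param reference paired reference values (mm)
#' @param target paired values in the units to be rescaled
#' @return a \code{scale_calibration} with \code{factor},
#'   \code{n_pairs} and \code{residual_rms} (in reference units).
#' @export
estimate_scale <- function(reference, target) {
  reference <- as.numeric(reference)
  target <- as.numeric(target)
  if (length(reference) != length(target)) {
    stop("reference and target must have equal length")
  }
  if (length(reference) < 2L) stop("need at least 2 pairs")
  if (any(!is.finite(reference) | !is.finite(target)) ||
      any(reference <= 0 | target <= 0)) {
    stop("all values must be positive and finite")
  }
  f <- sum(reference * target) / sum(target^2)
  structure(list(factor = f, n_pairs = length(reference),
                 residual_rms = sqrt(mean((reference - f * target)^2))),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("scale factor %.6f (n = %d, residual RMS %.4f mm)\n",
              x$factor, x$n_pairs, x$residual_rms))
  invisible(x)
}

# ---- method-comparison protocol --------------------------------------------

fdi_arch <- function(tooth_id) {
  q <- substr(gsub("[^0-9]", "", tooth_id), 1L, 1L)
  ifelse(q %in% c("1", "2"), "upper",
         ifelse(q %in% c("3", "4"), "lower", NA_character_))
}

fdi_group <- function(tooth_id) {
  p <- substr(gsub("[^0-9]", "", tooth_id), 2L, 2L)
  ifelse(p %in% c("1", "2"), "incisor",
         ifelse(p == "3", "canine",
                ifelse(p %in% c("4", "5"), "premolar",
                       ifelse(p %in% c("6", "7", "8"), "molar",
                              NA_character_))))
}

safe_shapiro <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(unique(x)) < 3L) {
    return(list(statistic = NA_real_, p = NA_real_, n = length(x),
                flag = "insufficient data"))
  }
  s <- stats::shapiro.test(x)
  list(statistic = unname(s$statistic), p = s$p.value, n = length(x),
       flag = "")
}

safe_wilcoxon <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) {
    return(list(statistic = NA_real_, p = NA_real_, n = length(x),
                flag = "insufficient data"))
  }
  if (all(x == y)) {
    # the exact signed-rank test is undefined with all-zero differences;
    # identical methods read as "no difference"
    return(list(statistic = 0, p = 1, n = length(x), flag = "degenerate"))
  }
  w <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                           exact = FALSE))
  list(statistic = unname(w$statistic), p = w$p.value, n = length(x),
       flag = "")
}

safe_kruskal <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2L || length(values) < 3L ||
      length(unique(values)) < 2L) {
    return(list(statistic = NA_real_, p = NA_real_, n = length(values),
                flag = "insufficient data"))
  }
  k <- stats::kruskal.test(values, groups)
  list(statistic = unname(k$statistic), p = k$p.value, n = length(values),
       flag = "")
}

#' Nonparametric method-comparison protocol
#'
#' Runs the measurement-comparison battery across the methods present in a
#' measurement table: Shapiro-Wilk normality per method and per paired
#' difference; paired Wilcoxon signed-rank tests for every method pair,
#' overall and stratified by dental arch and by tooth group (incisor /
#' canine / premolar / molar from the FDI number); and Kruskal-Wallis
#' omnibus tests across methods and across tooth groups of the paired
#' differences. Raw p-values are reported without multiplicity correction,
#' mirroring common practice in method-agreement studies; entries with too
#' few paired observations are flagged rather than dropped silently.
#'
#' @param table a measurement table (data.frame with columns
#'   \code{tooth_id}, \code{method}, \code{parameter}, \code{value_mm} and
#'   optionally \code{replicate}; replicates are averaged first).
#' @param methods optional subset of methods to compare (default: all
#'   methods present).
#' @return a \code{comparison_report}: list of data.frames
#'   \code{normality}, \code{pairwise}, \code{kruskal}.
#' @export
compare_methods <- function(table, methods = NULL) {
  table <- validate_measurement_table(table)
  if ("replicate" %in% names(table)) {
    table <- stats::aggregate(value_mm ~ tooth_id + method + parameter,
                              data = table, FUN = mean)
  }
  if (is.null(methods)) methods <- sort(unique(table$method))
  table <- table[table$method %in% methods, , drop = FALSE]
  if (length(methods) < 2L) stop("need at least 2 methods to compare")
  key <- function(d) paste(d$tooth_id, d$parameter, sep = "|")
  # normality per method
  norm_rows <- lapply(methods, function(m) {
    r <- safe_shapiro(table$value_mm[table$method == m])
    data.frame(series = m, statistic = r$statistic, p = r$p, n = r$n,
               flag = r$flag)
  })
  pair_rows <- list(); kw_rows <- list()
  pairs <- utils::combn(methods, 2L, simplify = FALSE)
  for (pr in pairs) {
    a <- table[table$method == pr[1], ]
    b <- table[table$method == pr[2], ]
    m <- merge(a, b, by = c("tooth_id", "parameter"),
               suffixes = c("_a", "_b"))
    lab <- paste(pr, collapse = " vs ")
    r <- safe_shapiro(m$value_mm_a - m$value_mm_b)
    norm_rows[[length(norm_rows) + 1L]] <-
      data.frame(series = paste0("diff: ", lab), statistic = r$statistic,
                 p = r$p, n = r$n, flag = r$flag)
    add_pair <- function(scope, sel) {
      r <- safe_wilcoxon(m$value_mm_a[sel], m$value_mm_b[sel])
      data.frame(comparison = lab, scope = scope, statistic = r$statistic,
                 p = r$p, n = r$n, flag = r$flag)
    }
    pair_rows[[length(pair_rows) + 1L]] <- add_pair("overall", rep(TRUE, nrow(m)))
    arch <- fdi_arch(m$tooth_id)
    for (ar in stats::na.omit(unique(arch))) {
      pair_rows[[length(pair_rows) + 1L]] <-
        add_pair(paste0("arch: ", ar), !is.na(arch) & arch == ar)
    }
    grp <- fdi_group(m$tooth_id)
    for (g in stats::na.omit(unique(grp))) {
      pair_rows[[length(pair_rows) + 1L]] <-
        add_pair(paste0("group: ", g), !is.na(grp) & grp == g)
    }
    rk <- safe_kruskal(m$value_mm_a - m$value_mm_b, grp)
    kw_rows[[length(kw_rows) + 1L]] <-
      data.frame(test = paste0("diff by tooth group: ", lab),
                 statistic = rk$statistic, p = rk$p, n = rk$n, flag = rk$flag)
  }
  rk <- safe_kruskal(table$value_mm, table$method)
  kw_rows[[length(kw_rows) + 1L]] <-
    data.frame(test = "values by method", statistic = rk$statistic,
               p = rk$p, n = rk$n, flag = rk$flag)
  structure(list(normality = do.call(rbind, norm_rows),
                 pairwise = do.call(rbind, pair_rows),
                 kruskal = do.call(rbind, kw_rows)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("== Normality (Shapiro-Wilk) ==\n"); print(x$normality, row.names = FALSE)
  cat("\n== Paired Wilcoxon signed-rank ==\n"); print(x$pairwise, row.names = FALSE)
  cat("\n== Kruskal-Wallis ==\n"); print(x$kruskal, row.names = FALSE)
  invisible(x)
}

validate_measurement_table <- function(table) {
  table <- as.data.frame(table)
  need <- c("tooth_id", "method", "parameter", "value_mm")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("measurement table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(table$value_mm) | table$value_mm <= 0)) {
    stop("value_mm must be positive and finite")
  }
  keycols <- intersect(c("tooth_id", "method", "parameter", "replicate"),
                       names(table))
  key <- do.call(paste, c(table[keycols], sep = "|"))
  if (anyDuplicated(key)) stop("duplicate (tooth, method, parameter) rows")
  table
}

#' Read / write measurement tables as CSV
#'
#' Columns: \code{tooth_id,method,parameter,value_mm} (plus optional
#' \code{replicate}); UTF-8, header required, decimal point.
#'
#' @param path CSV file path
#' @return \code{read_measurement_table}: a validated data.frame.
#' @export
read_measurement_table <- function(path) {
  validate_measurement_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                             colClasses = c(tooth_id = "character")))
}

#' @param table a measurement table data.frame
#' @rdname read_measurement_table
#' @export
write_measurement_table <- function(table, path) {
  utils::write.csv(validate_measurement_table(table), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
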