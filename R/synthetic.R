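#' Noise model for the synthetic acquisition chain
#'
#' Collects the perturbation settings that emulate the three measurement
#' routes and the segmentation chain: per-measurement landmark noise
#' (reference-point identification error, Gaussian, mm); panoramic
#' magnification, larger for vertical (height) than for horizontal (width)
#' dimensions, as panoramic projection geometry produces; a multiplicative
#' unit scale for CBCT-recorded values (device units per mm); and the
#' amplitude/wavelength of the smooth displacement field that turns a
#' ground-truth mesh into its "segmented" counterpart.
#'
#' Defaults: landmark sd 0.35 mm (compatible with the 0.4-0.6 mm
#' reference-point errors reported for panoramic measurements, and giving
#' Dahlberg errors well under 1 mm); PAN magnification 1.15 on heights and
#' 1.05 on widths (inside the 17-27% worst-case vertical magnification
#' envelope reported for panoramic imaging); CBCT unit scale 1/0.313854
#' (values recorded in device units, recovered by scale calibration);
#' mesh perturbation 0.3 mm RMS at 8 mm wavelength.
#'
#' @param landmark_sd per-measurement Gaussian noise sd (mm)
#' @param pan_magnification named vector with \code{height} and
#'   \code{width} multiplicative factors
#' @param cbct_scale device units per mm for CBCT-recorded values
#' @param mesh_perturbation_amplitude RMS vertex displacement (mm)
#' @param mesh_perturbation_wavelength displacement field wavelength (mm)
#' @return a \code{noise_model}
#' @export
noise_model <- function(landmark_sd = 0.35,
                        pan_magnification = c(height = 1.15, width = 1.05),
                        cbct_scale = 1 / 0.313854,
                        mesh_perturbation_amplitude = 0.3,
                        mesh_perturbation_wavelength = 8) {
  stopifnot(landmark_sd >= 0, all(pan_magnification > 0), cbct_scale > 0,
            mesh_perturbation_amplitude >= 0,
            mesh_perturbation_wavelength > 0)
  if (!all(c("height", "width") %in% names(pan_magnification))) {
    stop("pan_magnification needs named entries 'height' and 'width'")
  }
  structure(list(landmark_sd = landmark_sd,
                 pan_magnification = pan_magnification,
                 cbct_scale = cbct_scale,
                 mesh_perturbation_amplitude = mesh_perturbation_amplitude,
                 mesh_perturbation_wavelength = mesh_perturbation_wavelength),
            class = "noise_model")
}

# deterministic substream seed derived from a master seed and a label
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (seq_len(nchar(name)) * 131))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

height_params <- c("T_H", "C_H", "MC_H", "DC_H", "MT_H", "DT_H", "PT_H",
                   "H_FURC")
width_params <- c("EQU", "CEJ", "RAD", "MRAD", "DRAD", "PRAD")
crown_params <- c("EQU", "CEJ", "C_H", "MC_H", "DC_H")

#' Smoothly perturb a mesh
#'
#' Displaces vertices along a smooth pseudo-random vector field (a sum of
#' sinusoidal harmonics with seeded random directions and phases),
#' rescaled so the RMS vertex displacement equals \code{amplitude}
#' exactly. Topology is untouched, so closed meshes stay closed; at the
#' default amplitude/wavelength the field is far from self-intersecting.
#'
#' @param mesh a \code{triangle_mesh}
#' @param amplitude RMS displacement (mm); 0 returns the mesh unchanged
#' @param wavelength spatial wavelength of the field (mm)
#' @param seed integer seed (fully determines the field)
#' @param n_harmonics number of sinusoidal components
#' @return the perturbed \code{triangle_mesh}
#' @export
perturb_mesh <- function(mesh, amplitude, wavelength, seed,
                         n_harmonics = 6L) {
  stopifnot(amplitude >= 0, wavelength > 0)
  if (amplitude == 0) return(mesh)
  v <- mesh$vertices
  disp <- withr::with_seed(as.integer(seed), {
    d <- matrix(0, nrow(v), 3L)
    for (h in seq_len(n_harmonics)) {
      k <- stats::rnorm(3); k <- k / sqrt(sum(k^2))
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      phase <- stats::runif(1, 0, 2 * pi)
      s <- sin(2 * pi * (v %*% k) / wavelength + phase)
      d <- d + outer(as.vector(s), u)
    }
    d
  })
  rms <- sqrt(mean(rowSums(disp^2)))
  triangle_mesh(v + disp * (amplitude / rms), mesh$faces, validate = FALSE)
}

#' Default tooth roster
#'
#' Base (population-typical) parameter sets by FDI tooth number. The two
#' validation teeth are 2.1 (upper-left central incisor, single-rooted)
#' and 3.6 (lower-left first molar, two-rooted); \code{full = TRUE} adds a
#' full-arch roster (positions 1-7 in all four quadrants, premolars and
#' anteriors handled by the single-rooted builder, molars by the
#' multi-rooted one) so that the statistics protocol has teeth x methods
#' material to work on.
#'
#' @param full include all four quadrants (28 teeth) rather than only the
#'   two validation teeth?
#' @return a list of roster entries: \code{tooth_id}, \code{class},
#'   \code{params}.
#' @export
default_roster <- function(full = TRUE) {
  mono <- function(T_H, C_H, CEJ, EQU, RAD) {
    monoradicular_params(T_H, C_H, CEJ, EQU, RAD)
  }
  # typical crown/root dimensions by position (anterior to second molar)
  base <- list(
    "1" = mono(23.0, 10.5, 6.3, 8.5, 4.2),
    "2" = mono(21.5, 9.5, 5.8, 7.4, 3.9),
    "3" = mono(26.0, 10.0, 6.0, 7.8, 4.5),
    "4" = mono(21.0, 8.0, 5.5, 7.2, 4.0),
    "5" = mono(21.5, 7.8, 5.3, 7.0, 3.8),
    "6" = multiradicular_params(EQU = 11.0, CEJ = 9.0, MC_H = 7.5,
                                DC_H = 7.0, MT_H = 21.0, DT_H = 20.0,
                                MRAD = 3.5, DRAD = 3.2, H_FURC = 11.0),
    "7" = multiradicular_params(EQU = 10.5, CEJ = 8.6, MC_H = 7.0,
                                DC_H = 6.6, MT_H = 20.0, DT_H = 19.2,
                                MRAD = 3.3, DRAD = 3.0, H_FURC = 10.0)
  )
  entry <- function(q, p) {
    prm <- base[[as.character(p)]]
    list(tooth_id = sprintf("%d.%d", q, p),
         class = if (p >= 6) "molar" else "incisor",
         params = prm)
  }
  if (!full) return(list(entry(2L, 1L), entry(3L, 6L)))
  out <- list()
  for (q in 1:4) for (p in 1:7) out[[length(out) + 1L]] <- entry(q, p)
  out
}

# apply a per-tooth global size factor; homogeneous scaling preserves all
# parameter invariants
scale_params <- function(params, s) {
  vals <- Filter(Negate(is.null), unclass(params))
  vals <- lapply(vals, function(v) v * s)
  if (inherits(params, "monoradicular_params")) {
    do.call(monoradicular_params, vals)
  } else {
    do.call(multiradicular_params, vals)
  }
}

#' Simulate a multi-method measurement table
#'
#' Applies the method-specific transform, then landmark noise, to the true
#' parameters of each roster tooth: in-vivo records crown measures only
#' (truth + noise); PAN multiplies heights and widths by their
#' magnification factors before adding noise; CBCT records
#' \code{(truth + noise) * cbct_scale} in device units. Replicate
#' measurements (independent noise draws) feed the Dahlberg error.
#'
#' @param roster list of roster entries (see \code{\link{default_roster}})
#'   whose \code{params} are the true dimensions
#' @param method \code{"in_vivo"}, \code{"PAN"} or \code{"CBCT"}
#' @param noise a \code{noise_model}
#' @param replicates number of replicate measurement rounds (>= 1)
#' @param seed integer seed
#' @return a measurement table data.frame with a \code{replicate} column
#' @export
make_measurement_table <- function(roster, method, noise = noise_model(),
                                   replicates = 2L, seed = 1L) {
  if (!method %in% c("in_vivo", "PAN", "CBCT")) {
    stop("unknown method: ", method)
  }
  stopifnot(replicates >= 1L)
  rows <- withr::with_seed(substream_seed(seed, paste0("table_", method)), {
    out <- list()
    for (e in roster) {
      vals <- unlist(Filter(Negate(is.null), unclass(e$params)))
      if (method == "in_vivo") vals <- vals[names(vals) %in% crown_params]
      for (rep_i in seq_len(replicates)) {
        for (nm in names(vals)) {
          v <- vals[[nm]]
          v_noisy <- v + stats::rnorm(1, 0, noise$landmark_sd)
          rec <- switch(method,
            in_vivo = v_noisy,
            PAN = {
              mag <- if (nm %in% height_params)
                noise$pan_magnification[["height"]]
              else noise$pan_magnification[["width"]]
              v * mag + stats::rnorm(1, 0, noise$landmark_sd)
            },
            CBCT = v_noisy * noise$cbct_scale)
          out[[length(out) + 1L]] <- data.frame(
            tooth_id = e$tooth_id, method = method, parameter = nm,
            value_mm = max(rec, 0.05), replicate = rep_i)
        }
      }
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  rows
}

#' Generate a complete synthetic validation patient
#'
#' Produces everything the validation loop consumes, fully determined by
#' one seed: per-tooth true parameters (base roster dimensions times a
#' per-tooth anatomical size factor); ground-truth parametric meshes for
#' the build teeth; "segmented" counterparts (ground truth warped by a
#' smooth displacement field); blurred occupancy volumes standing in for
#' CBCT data around each segmented tooth; and in-vivo / PAN / CBCT
#' measurement tables with replicates.
#'
#' @param seed master integer seed; all randomness flows from it through
#'   named substreams
#' @param config list overriding any of: \code{noise} (a
#'   \code{noise_model}), \code{roster}, \code{build_ids} (tooth ids to
#'   mesh, default \code{c("2.1", "3.6")}), \code{resolution} (48),
#'   \code{replicates} (2), \code{anatomical_cv} (0.04), \code{voxel_mm}
#'   (0.4), \code{blur_sigma_voxels} (1)
#' @return a \code{synthetic_patient}: \code{teeth} (per build tooth:
#'   \code{truth} tooth_model, \code{segmented} mesh, \code{volume}),
#'   \code{table} (all methods, with replicates), \code{truth_roster},
#'   \code{generator_config}.
#' @export
generate_patient <- function(seed = 1L, config = list()) {
  cfg <- merge_config(
    list(noise = noise_model(), roster = default_roster(full = TRUE),
         build_ids = c("2.1", "3.6"), resolution = 48L, replicates = 2L,
         anatomical_cv = 0.04, voxel_mm = 0.4, blur_sigma_voxels = 1),
    config)
  roster <- cfg$roster
  for (e in roster) {
    if (!is.list(e) || !all(c("tooth_id", "class", "params") %in% names(e)) ||
        !inherits(e$params, "tooth_params")) {
      stop("invalid roster entry",
           if (is.list(e) && !is.null(e$tooth_id)) paste0(": tooth ", e$tooth_id))
    }
  }
  # anatomical size variation: one global factor per tooth
  sizes <- withr::with_seed(substream_seed(seed, "anatomy"), {
    stats::rnorm(length(roster), 1, cfg$anatomical_cv)
  })
  sizes <- pmin(pmax(sizes, 1 - 2 * cfg$anatomical_cv),
                1 + 2 * cfg$anatomical_cv)
  truth <- lapply(seq_along(roster), function(i) {
    e <- roster[[i]]
    e$params <- scale_params(e$params, sizes[i])
    e
  })
  teeth <- list()
  for (e in truth) {
    if (!e$tooth_id %in% cfg$build_ids) next
    model <- if (e$class == "incisor") {
      build_monoradicular(e$params, resolution = cfg$resolution)
    } else {
      build_multiradicular(e$params, resolution = cfg$resolution)
    }
    segm <- perturb_mesh(model$mesh,
                         cfg$noise$mesh_perturbation_amplitude,
                         cfg$noise$mesh_perturbation_wavelength,
                         substream_seed(seed, paste0("mesh_", e$tooth_id)))
    vol <- blur_volume(voxelize_mesh(segm, spacing = cfg$voxel_mm),
                       sigma = cfg$blur_sigma_voxels)
    teeth[[e$tooth_id]] <- list(tooth_id = e$tooth_id, class = e$class,
                                truth = model, segmented = segm,
                                volume = vol)
  }
  tabs <- lapply(c("in_vivo", "PAN", "CBCT"), function(m)
    make_measurement_table(truth, m, cfg$noise, cfg$replicates, seed))
  structure(list(seed = seed, teeth = teeth,
                 table = do.call(rbind, tabs),
                 truth_roster = truth, generator_config = cfg),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient: seed %d, %d roster teeth, %d meshed, %d table rows>\n",
              x$seed, length(x$truth_roster), length(x$teeth),
              nrow(x$table)))
  invisible(x)
}
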