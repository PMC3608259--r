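#' Run the full synthetic validation pipeline
#'
#' Executes the end-to-end loop on one synthetic patient: simulate
#' (meshes, volumes, measurement tables) -> Dahlberg repeatability per
#' method -> CBCT unit-scale calibration against in-vivo crown measures ->
#' panoramic magnification calibration (heights and widths separately)
#' against calibrated CBCT -> nonparametric method comparison -> parametric
#' model building from the calibrated panoramic measures -> segmentation
#' threshold calibration on the volume -> best-fit superimposition of the
#' parametric model on the segmented mesh -> signed deviation map and
#' per-region report.
#'
#' @param config list overriding any of: \code{seed} (42), \code{outdir}
#'   (NULL: no artifacts written), \code{patient} (options for
#'   \code{\link{generate_patient}}), \code{tau_grid} (thresholds scanned
#'   on the blurred occupancy volumes), \code{align} (options for
#'   \code{\link{best_fit_align}}), \code{verbose} (TRUE: stage-tagged log
#'   lines on stderr).
#' @return a \code{pipeline_result} list: \code{scale} (CBCT factor and
#'   PAN height/width factors), \code{dahlberg} (per method, mm),
#'   \code{stats} (a \code{comparison_report}), \code{teeth} (per built
#'   tooth: calibrated parameters, threshold calibration, ICP fit,
#'   deviation report), \code{artifacts} (paths written, if any).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(
    list(seed = 42L, outdir = NULL, patient = list(),
         tau_grid = seq(0.2, 0.8, by = 0.15), align = list(),
         verbose = TRUE), config)
  log_line <- function(stage, ...) {
    if (isTRUE(cfg$verbose)) {
      message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"),
                      stage, sprintf(...)))
    }
  }
  artifacts <- character(0)
  emit <- function(fname, writer) {
    if (is.null(cfg$outdir)) return(invisible(NULL))
    if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
    p <- file.path(cfg$outdir, fname)
    writer(p)
    artifacts <<- c(artifacts, p)
    p
  }

  log_line("simulate", "generating synthetic patient (seed %d)", cfg$seed)
  patient <- generate_patient(cfg$seed, cfg$patient)
  tab <- patient$table
  emit("measurements.csv", function(p) write_measurement_table(tab, p))

  # replicate means per (tooth, method, parameter)
  means <- stats::aggregate(value_mm ~ tooth_id + method + parameter,
                            data = tab, FUN = mean)
  get_vals <- function(m) means[means$method == m, ]

  # CBCT unit scale from in-vivo crown measures
  iv <- get_vals("in_vivo"); cb <- get_vals("CBCT")
  mrg <- merge(iv, cb, by = c("tooth_id", "parameter"))
  cal_cbct <- estimate_scale(mrg$value_mm.x, mrg$value_mm.y)
  log_line("scale", "CBCT unit factor %.6f (residual RMS %.3f mm)",
           cal_cbct$factor, cal_cbct$residual_rms)

  cbct_mm <- get_vals("CBCT")
  cbct_mm$value_mm <- cbct_mm$value_mm * cal_cbct$factor
  pan <- get_vals("PAN")
  pan_h <- merge(cbct_mm[cbct_mm$parameter %in% height_params, ],
                 pan[pan$parameter %in% height_params, ],
                 by = c("tooth_id", "parameter"))
  pan_w <- merge(cbct_mm[cbct_mm$parameter %in% width_params, ],
                 pan[pan$parameter %in% width_params, ],
                 by = c("tooth_id", "parameter"))
  cal_h <- estimate_scale(pan_h$value_mm.x, pan_h$value_mm.y)
  cal_w <- estimate_scale(pan_w$value_mm.x, pan_w$value_mm.y)
  log_line("scale", "PAN factors: heights %.4f, widths %.4f",
           cal_h$factor, cal_w$factor)
  pan_cal <- pan
  pan_cal$value_mm <- pan$value_mm *
    ifelse(pan$parameter %in% height_params, cal_h$factor, cal_w$factor)

  # Dahlberg per method on the millimetre scale
  dahl <- vapply(c("in_vivo", "PAN", "CBCT"), function(m) {
    sub <- tab[tab$method == m & tab$replicate %in% 1:2, ]
    wide <- merge(sub[sub$replicate == 1, c("tooth_id", "parameter", "value_mm")],
                  sub[sub$replicate == 2, c("tooth_id", "parameter", "value_mm")],
                  by = c("tooth_id", "parameter"))
    s <- if (m == "CBCT") cal_cbct$factor else 1
    dahlberg_error(cbind(wide$value_mm.x, wide$value_mm.y) * s)$S_D
  }, numeric(1))
  log_line("dahlberg", "S_D (mm): %s",
           paste(sprintf("%s %.3f", names(dahl), dahl), collapse = ", "))

  # method comparison on the calibrated tables
  iv_tab <- get_vals("in_vivo")
  stats_tab <- rbind(iv_tab, pan_cal, cbct_mm)
  report <- compare_methods(stats_tab)
  emit("stats.json", function(p)
    jsonlite::write_json(unclass(report), p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows"))

  teeth_out <- list()
  for (tid in names(patient$teeth)) {
    tooth <- patient$teeth[[tid]]
    vals <- pan_cal[pan_cal$tooth_id == tid, ]
    prm <- stats::setNames(vals$value_mm, vals$parameter)
    params_hat <- params_from_measures(prm, tooth$class)
    log_line("build", "tooth %s: rebuilding from calibrated PAN measures", tid)
    model <- if (tooth$class == "incisor") {
      build_monoradicular(params_hat,
                          resolution = patient$generator_config$resolution)
    } else {
      build_multiradicular(params_hat,
                           resolution = patient$generator_config$resolution)
    }
    log_line("calibrate", "tooth %s: threshold scan over %d levels", tid,
             length(cfg$tau_grid))
    thr <- calibrate_threshold(tooth$volume, tooth$segmented, cfg$tau_grid,
                               align_config = cfg$align)
    log_line("calibrate", "tooth %s: tau* = %.3f", tid, thr$tau_star)
    fit <- best_fit_align(model$mesh, tooth$segmented, config = cfg$align)
    aligned <- transform_mesh(model$mesh, fit$transform$rotation,
                              fit$transform$translation)
    dmap <- signed_distance_map(aligned, tooth$segmented)
    rep_t <- deviation_report(dmap, aligned)
    log_line("compare",
             "tooth %s: ICP rms %.3f mm; mean |d| %.3f mm; signed extremes [%.2f, %.2f] mm",
             tid, fit$rms, attr(rep_t, "overall_mean_abs"),
             attr(rep_t, "overall_min_signed"), attr(rep_t, "overall_max_signed"))
    emit(sprintf("tooth_%s_parametric.stl", gsub("[.]", "", tid)),
         function(p) write_stl(aligned, p))
    emit(sprintf("tooth_%s_segmented.stl", gsub("[.]", "", tid)),
         function(p) write_stl(tooth$segmented, p))
    emit(sprintf("tooth_%s_deviation.ply", gsub("[.]", "", tid)),
         function(p) write_ply(aligned, p, scalar = as.numeric(dmap)))
    teeth_out[[tid]] <- list(tooth_id = tid, class = tooth$class,
                             params_hat = params_hat, threshold = thr,
                             fit = fit, deviation = rep_t)
  }
  result <- structure(
    list(seed = cfg$seed,
         scale = list(cbct = cal_cbct, pan_height = cal_h, pan_width = cal_w),
         dahlberg = dahl, stats = report, teeth = teeth_out,
         artifacts = artifacts),
    class = "pipeline_result")
  emit("summary.json", function(p) {
    summ <- list(
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("toothrecon")),
      scale_factor_cbct = cal_cbct$factor,
      pan_height_factor = cal_h$factor, pan_width_factor = cal_w$factor,
      dahlberg_mm = as.list(dahl),
      teeth = lapply(teeth_out, function(t) list(
        tau_star = t$threshold$tau_star, icp_rms = t$fit$rms,
        mean_abs_deviation = attr(t$deviation, "overall_mean_abs"),
        max_abs_deviation = attr(t$deviation, "overall_max_abs"))))
    jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA)
  })
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: seed %d>\n", x$seed))
  cat(sprintf("  CBCT scale factor: %.6f\n", x$scale$cbct$factor))
  cat(sprintf("  PAN factors: heights %.4f, widths %.4f\n",
              x$scale$pan_height$factor, x$scale$pan_width$factor))
  cat("  Dahlberg S_D (mm):", paste(sprintf("%s %.3f", names(x$dahlberg),
                                            x$dahlberg), collapse = ", "), "\n")
  for (t in x$teeth) {
    cat(sprintf("  tooth %s: tau* %.3f, ICP rms %.3f mm, mean |d| %.3f mm\n",
                t$tooth_id, t$threshold$tau_star, t$fit$rms,
                attr(t$deviation, "overall_mean_abs")))
  }
  invisible(x)
}

# build a parameter record from (noisy) measured values, with gentle
# clamping of order invariants that measurement noise can violate
params_from_measures <- function(vals, tooth_class) {
  g <- function(nm) if (nm %in% names(vals)) unname(vals[[nm]]) else NULL
  if (tooth_class == "incisor") {
    CEJ <- min(g("CEJ"), g("EQU"))
    RAD <- min(g("RAD"), CEJ)
    C_H <- min(g("C_H"), 0.95 * g("T_H"))
    monoradicular_params(T_H = g("T_H"), C_H = C_H, CEJ = CEJ,
                         EQU = g("EQU"), RAD = RAD)
  } else {
    mc <- min(g("MC_H"), 0.95 * g("MT_H"))
    dc <- min(g("DC_H"), 0.95 * g("DT_H"))
    hf <- g("H_FURC")
    max_hf <- 0.95 * min(g("MT_H") - mc, g("DT_H") - dc)
    if (!is.null(hf)) hf <- min(hf, max_hf)
    multiradicular_params(EQU = g("EQU"), CEJ = min(g("CEJ"), g("EQU")),
                          MC_H = mc, DC_H = dc, MT_H = g("MT_H"),
                          DT_H = g("DT_H"), MRAD = g("MRAD"),
                          DRAD = g("DRAD"), PRAD = g("PRAD"),
                          PT_H = g("PT_H"), H_FURC = hf)
  }
}
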