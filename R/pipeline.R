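#' Pipeline configuration
#'
#' @param sessions List of session descriptors, in temporal order. Each is
#'   either `list(type = "simulate", change = <change_spec or NULL>)`
#'   (sessions after the first are derived from the previous scene by
#'   [apply_longitudinal_change()]) or `list(type = "tiles", paths =
#'   c(t00, t01, t10, t11))` pointing at TIFF tiles on disk.
#' @param baseline Index of the baseline session.
#' @param seed Master seed; per-stage seeds are derived from it by stage
#'   name ([derive_seed()]), so adding stages never perturbs earlier ones.
#' @param sim_config [simulation_config()] used by simulated sessions.
#' @param overlap_px Tile overlap used when simulating acquisition.
#' @param output_dir Directory for metrics CSV / report JSON (`NULL` = do
#'   not write).
#' @param stage_params Named list of per-stage parameter overrides:
#'   `segmentation` ([segmentation_params()]), `conversion`
#'   ([conversion_params()]), `trace` ([trace_params()]), `icp` (options
#'   list), `radius_threshold`, `boundary_margin`, `match_tol`.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(sessions, baseline = 1L, seed = 1L,
                            sim_config = simulation_config(),
                            overlap_px = 24L, output_dir = NULL,
                            stage_params = list()) {
  if (length(sessions) < 1) stopf("session manifest must be non-empty")
  if (baseline < 1 || baseline > length(sessions))
    stopf("baseline id must be present in the manifest")
  structure(list(sessions = sessions, baseline = as.integer(baseline),
                 seed = as.integer(seed), sim_config = sim_config,
                 overlap_px = as.integer(overlap_px),
                 output_dir = output_dir, stage_params = stage_params),
            class = "pipeline_config")
}

stage_try <- function(stage, session, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed for session %s: %s", stage, session,
          conditionMessage(e)))
}

#' Run the full longitudinal pipeline
#'
#' Executes simulate-or-load, stitching, autofluorescence segmentation and
#' removal, depth-adaptive 8-bit conversion with cross-session
#' normalization, registration of every session to the baseline, cropping
#' to the largest common volume, fiber tracing with caliber
#' classification, and structural-plasticity quantification. Every stage's
#' parameters and derived seeds are recorded in the report for exact
#' replay.
#'
#' @param config A [pipeline_config()].
#' @return List: `metrics` (per-session data frame), `graphs` (traced
#'   `fiber_graph`s in the common frame), `report` (stage record),
#'   `ground_truth` (per-session scenes for simulated manifests),
#'   `common_box`.
#' @export
run_pipeline <- function(config) {
  sp <- config$stage_params
  seg_par <- sp$segmentation %||% segmentation_params()
  conv_par <- sp$conversion %||% conversion_params()
  trc_par <- sp$trace %||% trace_params()
  icp_opts <- sp$icp %||% list()
  # caliber radii measured on registered, resampled 8-bit stacks carry a
  # positive bias (interpolation widening, residual registration error),
  # so the longitudinal cut sits higher than the clean-stack default
  rad_thr <- sp$radius_threshold %||% 1.2
  margin <- sp$boundary_margin %||% 3
  ns <- length(config$sessions)
  report <- list(seed = config$seed, stages = list())
  scenes <- vector("list", ns)
  supers <- vector("list", ns)
  labels <- vector("list", ns)
  # --- acquire + stitch ---
  prev_scene <- NULL
  for (i in seq_len(ns)) {
    ses <- config$sessions[[i]]
    if (identical(ses$type, "tiles")) {
      missing <- ses$paths[!file.exists(ses$paths)]
      if (length(missing) > 0)
        stopf("I/O error for session %s: missing input %s", i, missing[1])
      tiles <- stage_try("load", i, {
        tl <- lapply(ses$paths, read_stack)
        names(tl) <- c("t00", "t01", "t10", "t11")
        tl
      })
    } else {
      sseed <- derive_seed(config$seed, paste0("simulate", i))
      scene <- stage_try("simulate", i, {
        if (i == 1 || is.null(prev_scene))
          scene_baseline(config$sim_config, sseed)
        else
          apply_longitudinal_change(prev_scene, ses$change %||% list(),
                                    sseed)
      })
      prev_scene <- scene
      scenes[[i]] <- scene
      rseed <- derive_seed(config$seed, paste0("render", i))
      rend <- stage_try("render", i,
                        render_stack(deformed_skeleton(scene),
                                     config$sim_config, rseed))
      tiles <- stage_try("tiling", i,
                         make_quadrant_tiles(rend$stack,
                                             config$overlap_px)$tiles)
    }
    nominal <- config$overlap_px / dim(tiles$t00$data)[1]
    supers[[i]] <- stage_try("stitch", i,
                             stitch_quadrants(tiles,
                                              nominal_overlap_frac = nominal))
    report$stages[[paste0("stitch_s", i)]] <-
      attr(supers[[i]], "provenance")$offsets
  }
  # --- segment + clean ---
  cleaned <- vector("list", ns)
  for (i in seq_len(ns)) {
    labels[[i]] <- stage_try("segment", i,
                             semi_supervised_segment(supers[[i]],
                                                     params = seg_par))
    cleaned[[i]] <- stage_try("clean", i,
                              remove_autofluorescence(supers[[i]],
                                                      labels[[i]]))
  }
  # --- convert + cross-session normalize ---
  conv <- stage_try("convert", "all",
                    cross_session_normalize(cleaned, conv_par))
  # --- register to baseline ---
  b <- config$baseline
  transforms <- vector("list", ns)
  clouds <- lapply(seq_len(ns), function(i) {
    stage_try("pointcloud", i,
              extract_point_cloud(conv[[i]],
                                  seed = derive_seed(config$seed,
                                                     paste0("cloud", i)),
                                  mask = labels[[i]] == 1L))
  })
  for (i in seq_len(ns)) {
    if (i == b || clouds[[i]]$empty || clouds[[b]]$empty) {
      transforms[[i]] <- session_transform()
    } else {
      transforms[[i]] <- stage_try("register", i,
                                   register_session(clouds[[i]],
                                                    clouds[[b]], icp_opts))
    }
  }
  # --- crop to largest common volume ---
  cropped <- stage_try("crop", "all",
                       crop_common_volume(conv, transforms, labels))
  odims <- dim(cropped$stacks[[1]]$data)
  vox <- cropped$stacks[[1]]$voxel_size
  roi <- rbind(lo = c(0, 0, 0), hi = (odims - 1) * vox)
  # --- trace + classify (geometry from the segmentation's fiber class,
  # intensities only for radius estimation) ---
  graphs <- lapply(seq_len(ns), function(i) {
    g <- stage_try("trace", i,
                   trace_fibers(cropped$stacks[[i]], trc_par,
                                mask = cropped$labels[[i]] == 1L))
    if (nrow(g$edges) > 0) g <- classify_fiber_caliber(g, rad_thr)
    g
  })
  # --- quantify ---
  surface <- tryCatch(
    estimate_epidermal_boundary(cropped$labels[[b]], voxel_size = vox),
    error = function(e) NULL)
  metrics <- stage_try("quantify", "all",
                       longitudinal_metrics(graphs, baseline_index = b,
                                            common_roi = roi,
                                            surface = surface,
                                            boundary_margin = margin))
  report$stages$common_box <- cropped$box
  report$params <- list(segmentation = unclass(seg_par),
                        conversion = unclass(conv_par),
                        trace = unclass(trc_par),
                        radius_threshold = rad_thr,
                        boundary_margin = margin,
                        overlap_px = config$overlap_px,
                        baseline = b)
  out <- list(metrics = metrics, graphs = graphs, report = report,
              ground_truth = scenes, common_box = cropped$box,
              surface = surface, cropped_labels = cropped$labels)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics_csv(metrics, file.path(config$output_dir, "metrics.csv"))
    jsonlite::write_json(report,
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
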