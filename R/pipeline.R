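#' Default pipeline configuration
#'
#' Assembles the run configuration for [run_pipeline()]: scene parameters,
#' classification thresholds, terrain-interpolation settings, calibration
#' rules and the accuracy-assessment design, with the analysis defaults
#' throughout. Any element can be overridden by passing a partial list.
#'
#' @param seed integer seed controlling every random stage.
#' @param out_dir output directory (created if missing).
#' @param stages character vector of stages to write outputs for, in the
#'   fixed topological order `simulate`, `composite`, `classify`, `patches`,
#'   `dtm`, `chm`, `calibrate`, `account`, `accuracy`. Dependencies of a
#'   requested stage are computed in memory but only requested stages write.
#' @param scene named list of [scene_params()] overrides.
#' @param thresholds named list of [threshold_config()] overrides.
#' @param idw list with `power` and `radius`. The pipeline default search
#'   radius (300 m, roughly six times the mean bare-ground point spacing)
#'   keeps the interpolation local; with global support, inverse-distance
#'   weights pull the surface toward the regional mean over trending
#'   terrain, which inflates terrain error under the canopy.
#' @param gcps list with `n` and `holdout` (bare-ground sample sizes).
#' @param calibration list with `min_height`, `cap_percentile`, `plot_m`.
#' @param accuracy list with `n_per_class`, `buffer_m`.
#' @return a config list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("tofscape_run_"),
                            stages = c("simulate", "composite", "classify",
                                       "patches", "dtm", "chm", "calibrate",
                                       "account", "accuracy"),
                            scene = list(), thresholds = list(),
                            idw = list(power = 2, radius = 300),
                            gcps = list(n = 820, holdout = 40),
                            calibration = list(min_height = 2.19,
                                               cap_percentile = 99,
                                               plot_m = 100),
                            accuracy = list(n_per_class = 500, buffer_m = 10)) {
  all_stages <- c("simulate", "composite", "classify", "patches", "dtm",
                  "chm", "calibrate", "account", "accuracy")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 stages = all_stages[all_stages %in% stages],
                 scene = scene, thresholds = thresholds, idw = idw,
                 gcps = gcps, calibration = calibration, accuracy = accuracy),
            class = "run_config")
}

#' Run the TOF analysis pipeline
#'
#' Orchestrates simulate -> composite -> classify -> patches -> dtm -> chm ->
#' calibrate -> account -> accuracy as one configured, logged run. Stage
#' products are written under `out_dir` (rasters as TIFF with JSON sidecar,
#' tables as CSV, reports as JSON) and listed in a run manifest with MD5
#' checksums; a rerun with the same config and seed is bit-identical for the
#' deterministic stages. A stage failure halts the run with the stage name
#' in the error.
#'
#' @param config a [pipeline_config()] list, a plain named list of its
#'   fields, or the path to a YAML file holding them.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "run_config"))
    config <- do.call(pipeline_config, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  res <- list(config = config)
  emit <- function(path) outputs <<- c(outputs, path)
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  want <- function(name) name %in% config$stages
  od <- function(f) file.path(config$out_dir, f)

  # --- simulate (always computed: everything downstream consumes it)
  res$truth <- stage("simulate", function() {
    params <- do.call(scene_params, c(config$scene, list(seed = config$seed)))
    generate_landscape(params)
  })
  if (want("simulate")) {
    emit(write_raster(res$truth$tree_mask, od("truth_tree_mask.tif")))
    emit(write_raster(res$truth$tree_height, od("truth_tree_height.tif")))
    emit(write_raster(res$truth$terrain, od("truth_terrain.tif")))
    emit(write_polygons(res$truth$division_polygons, od("divisions.geojson")))
    if (length(res$truth$forest_exclusion))
      emit(write_polygons(res$truth$forest_exclusion, od("forest_exclusion.geojson")))
  }
  last <- utils::tail(config$stages, 1L)
  if (last == "simulate") return(invisible(finish_run(res, config, outputs)))

  # --- composite
  cfg <- do.call(threshold_config, config$thresholds)
  res$composites <- stage("composite", function() {
    optical <- render_optical_series(res$truth)
    sar <- render_sar_series(res$truth)
    list(optical = greenest_composite(optical),
         sar = sar_composite(sar$ascending, sar$descending))
  })
  if (want("composite")) {
    emit(write_raster(res$composites$optical$ndvi, od("ndvi_composite.tif")))
    emit(write_raster(res$composites$sar$vh_db, od("vh_mean_db.tif")))
    emit(write_raster(res$composites$sar$vv_db, od("vv_mean_db.tif")))
  }

  # --- classify
  res$tof_mask <- stage("classify", function()
    classify_tof(res$composites$optical$ndvi, res$composites$sar$vh_db,
                 res$composites$sar$vv_db, res$truth$forest_exclusion, cfg))
  if (want("classify")) emit(write_raster(res$tof_mask, od("tof_mask.tif")))

  # --- patches
  if (want("patches")) {
    res$patches <- stage("patches", function() {
      labels <- label_patches(res$tof_mask, connectivity = 4L)
      tab <- patch_table(labels)
      list(labels = labels, table = tab, summary = size_class_summary(tab))
    })
    utils::write.csv(res$patches$table, od("patches.csv"), row.names = FALSE)
    utils::write.csv(res$patches$summary, od("patch_summary.csv"),
                     row.names = FALSE)
    emit(od("patches.csv")); emit(od("patch_summary.csv"))
  }

  # --- dtm
  res$dtm <- stage("dtm", function() {
    pts <- sample_gcps(res$truth, n = config$gcps$n,
                       holdout = config$gcps$holdout,
                       seed = config$seed + 41L)
    list(points = pts,
         result = build_dtm(pts$gcps, pts$holdout, res$truth$terrain,
                            power = config$idw$power,
                            radius = config$idw$radius))
  })
  if (want("dtm")) {
    emit(write_gcps(res$dtm$points$gcps, od("gcps.csv")))
    emit(write_raster(res$dtm$result$dtm, od("dtm.tif")))
    jsonlite::write_json(list(rmse_holdout_m = res$dtm$result$rmse_holdout,
                              n_gcp = res$dtm$result$n_gcp,
                              n_holdout = res$dtm$result$n_holdout,
                              idw_power = res$dtm$result$idw_power),
                         od("dtm_report.json"), auto_unbox = TRUE, digits = NA)
    emit(od("dtm_report.json"))
  }

  # --- chm
  res$surfaces <- stage("chm", function() render_dsm(res$truth))
  res$chm <- stage("chm", function()
    canopy_height(res$surfaces$dsm, res$dtm$result$dtm, res$tof_mask))
  if (want("chm")) emit(write_raster(res$chm, od("chm_raw.tif")))

  # --- calibrate
  res$calibration <- stage("calibrate", function() {
    ref_chm <- canopy_height(res$surfaces$reference_dsm, res$dtm$result$dtm,
                             res$tof_mask)
    plots <- aggregate_plots(res$chm, ref_chm, res$tof_mask,
                             plot_m = config$calibration$plot_m)
    kept <- exclude_outliers(plots)
    model <- fit_calibration(kept,
                             min_height = config$calibration$min_height,
                             cap_percentile = config$calibration$cap_percentile)
    list(plots = plots, model = model,
         chm = apply_calibration(res$chm, model, res$truth$division_labels))
  })
  if (want("calibrate")) {
    utils::write.csv(res$calibration$plots, od("calibration_plots.csv"),
                     row.names = FALSE)
    emit(od("calibration_plots.csv"))
    m <- res$calibration$model
    jsonlite::write_json(unclass(m), od("calibration_model.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(od("calibration_model.json"))
    emit(write_raster(res$calibration$chm, od("chm_calibrated.tif")))
  }

  # --- account
  if (want("account")) {
    res$accounting <- stage("account", function() {
      list(divisions = division_summary(res$tof_mask,
                                        res$truth$division_polygons),
           heights = height_summary(res$calibration$chm,
                                    res$truth$division_labels))
    })
    ht <- res$accounting$heights
    ht$division <- c(res$truth$division_polygons$names, "Total")[
      match(ht$division, c(as.character(seq_len(8)), "Total"))]
    res$accounting$heights <- ht
    utils::write.csv(res$accounting$divisions, od("division_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(ht, od("height_summary.csv"), row.names = FALSE)
    emit(od("division_summary.csv")); emit(od("height_summary.csv"))
  }

  # --- accuracy
  if (want("accuracy")) {
    res$accuracy <- stage("accuracy", function() {
      pts <- sample_validation_points(res$tof_mask,
                                      res$truth$division_polygons,
                                      n_per_class = config$accuracy$n_per_class,
                                      seed = config$seed + 51L)
      pts$ref_label <- extract_at(res$truth$tree_mask, pts$x, pts$y)
      counts <- validate_points(res$tof_mask, pts,
                                buffer_m = config$accuracy$buffer_m)
      areas <- stratum_areas(res$tof_mask, res$truth$division_polygons)
      stratified_accuracy(counts, areas[unique(counts$stratum)])
    })
    jsonlite::write_json(
      list(overall_accuracy = res$accuracy$overall_accuracy,
           users_accuracy = as.list(res$accuracy$users_accuracy),
           producers_accuracy = as.list(res$accuracy$producers_accuracy),
           area_estimates = res$accuracy$area_estimates),
      od("accuracy_report.json"), auto_unbox = TRUE, digits = NA)
    emit(od("accuracy_report.json"))
  }

  invisible(finish_run(res, config, outputs))
}

finish_run <- function(res, config, outputs) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("tofscape")),
    seed = config$seed, stages = config$stages,
    parameters = list(scene = config$scene, thresholds = config$thresholds,
                      idw = config$idw, gcps = config$gcps,
                      calibration = config$calibration,
                      accuracy = config$accuracy),
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res
}
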