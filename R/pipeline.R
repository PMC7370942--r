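# End-to-end pipeline: cloud -> fiducial clusters -> RANSAC labels ->
# head transform -> interpolated channel positions in reference space.

pipeline_log <- function(logfile, fmt, ...) {
  line <- sprintf(fmt, ...)
  message("[capreg] ", line)
  if (!is.na(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

#' Run the full co-registration pipeline
#'
#' Executes extract -> label -> fit -> project on a subject point cloud:
#' sticker-colored vertices are clustered into fiducial centroids, labeled
#' by RANSAC against the model cap, the head fiducials (Nz, AL, AR, Cz) are
#' fit to the reference MNI fiducials by rotation + AP/LR scaling +
#' translation, and channel positions are interpolated from the model cap's
#' barycentric weights. Every stage logs its parameters and counts; when
#' `output_dir` is set, labeled fiducials and channel positions are written
#' there as CSV. Deterministic for a fixed seed.
#'
#' @param config a [pipeline_config()] (or path to one, YAML/JSON).
#' @param cloud optional [colored_point_cloud()] overriding
#'   `config$ply_path`.
#' @param model optional `model_cap` overriding `config$model_cap_path`.
#' @param reference optional [fiducial_set()] overriding
#'   `config$reference_mni_path`.
#' @return A [session_measurement()] of interpolated channel positions;
#'   attributes `"labeling"` (the [label_fiducials()] result) and
#'   `"head_transform"` carry the intermediate fits.
#' @export
run_pipeline <- function(config, cloud = NULL, model = NULL,
                         reference = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  logfile <- NA_character_
  if (!is.na(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    logfile <- file.path(config$output_dir, "pipeline.log")
  }
  pipeline_log(logfile, "run_pipeline start; seed %d; config %s",
               config$seed, config_hash(config))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_capreg("pipeline_error",
                  sprintf("stage '%s' failed: %s (check the %s inputs and config)",
                          name, conditionMessage(e), name))
    })
  }

  if (is.null(cloud)) {
    if (is.na(config$ply_path))
      stop_capreg("invalid_parameter",
                  "no point cloud: set `ply_path` or pass `cloud`")
    cloud <- stage("read", read_point_cloud(config$ply_path))
  }
  pipeline_log(logfile, "cloud: %d vertices", nrow(cloud$positions))

  if (is.null(model)) {
    if (is.na(config$model_cap_path))
      stop_capreg("invalid_parameter",
                  "no model cap: set `model_cap_path` or pass `model`")
    model <- stage("model", read_model_cap_csv(config$model_cap_path))
  }
  if (is.null(reference))
    reference <- stage("reference",
                       read_fiducials_csv(config$reference_mni_path))

  centroids <- stage("extract",
                     extract_fiducial_clusters(
                       cloud, sticker_hue = config$sticker_hue,
                       hue_tol = config$hue_tol,
                       link_radius_mm = config$link_radius_mm,
                       min_cluster_size = config$min_cluster_size))
  pipeline_log(logfile,
               "extract: %d clusters (hue %.3f +/- %.3f, link %.1f mm, min %d)",
               nrow(centroids), config$sticker_hue, config$hue_tol,
               config$link_radius_mm, config$min_cluster_size)

  labeling <- stage("label",
                    label_fiducials(centroids, model$fiducials,
                                    seed = config$seed))
  pipeline_log(logfile, "label: %d points labeled, fit cost %.3f mm",
               labeling$n_points_used, labeling$fit_cost_mm)

  tf <- stage("fit", fit_head_transform(labeling$fiducials, reference))
  pipeline_log(logfile,
               "fit: residual %.4f mm, scales LR %.4f AP %.4f",
               attr(tf, "residual_mm"), tf$scale_lr, tf$scale_ap)

  measurement <- stage("project",
                       project_channels(model, labeling$fiducials, tf,
                                        session_id = sprintf("seed%d",
                                                             config$seed)))
  pipeline_log(logfile, "project: %d channels interpolated",
               nrow(measurement$channel_positions))

  if (!is.na(config$output_dir)) {
    write_fiducials_csv(labeling$fiducials,
                        file.path(config$output_dir, "fiducials.csv"))
    write_channels_csv(measurement,
                       file.path(config$output_dir, "channels.csv"))
  }
  attr(measurement, "labeling") <- labeling
  attr(measurement, "head_transform") <- tf
  measurement
}
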