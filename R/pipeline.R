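#' Pipeline configuration
#'
#' Collects every tunable of the workflow with its default. Unknown keys are
#' rejected; values are validated before any stage runs.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # input: either a cloud file or a simulated stage
    input = NULL, simulate = NULL, cultivar = "moderate", seed = 1L,
    noise_sd = 0.02, outlier_frac = 0.01, true_scale = 1, tilt_deg = 0,
    out_dir = tempfile("wheatpheno_run_"),
    # restoration
    real_width = 3, virtual_width = NULL, white_thresh = 200,
    dist_thresh = 0.2, ransac_iters = 1000,
    # plant extraction
    alpha = 0.3, eps = 1, min_size = 50, voxel = 0.5,
    gr_thresh = 5, gb_thresh = 30, sor_k = 10, sor_ratio = 3,
    # segmentation
    k_geom = 30, angle_thresh = 8, curv_thresh = 0.05, min_region = 100,
    # phenotyping
    crown_mode = "diameter", surface_voxel = 0.2, leaf_voxel = 0.2,
    stations = 30, span = 0.3, degree = 2, bp_radii = NULL,
    # stage list: trailing stages may be skipped, order is fixed
    stages = c("simulate", "preprocess", "segment", "phenotype", "validate")
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, overrides, keep.null = TRUE)
  full <- c("simulate", "preprocess", "segment", "phenotype", "validate")
  cfg$stages <- intersect(full, cfg$stages)
  if (!identical(cfg$stages, full[seq_along(cfg$stages)])) {
    abort("stages must be a prefix of simulate > preprocess > segment > phenotype > validate")
  }
  if (is.null(cfg$input) && is.null(cfg$simulate)) {
    abort("config needs either `input` (a cloud file) or `simulate` (a stage name)")
  }
  if (!is.null(cfg$input) && !file.exists(cfg$input)) {
    abort(paste0("input cloud not found: ", cfg$input))
  }
  if (cfg$alpha < 0 || cfg$alpha > 1) abort("alpha must lie in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Run the full phenotyping pipeline
#'
#' Executes simulate (or read) > restore scale and frame > extract plant >
#' region-growing segmentation > phenotype extraction > validation against
#' ground truth (simulated scenes only), writing per-stage artifacts and a
#' manifest into `config$out_dir`. Stage order is fixed; `config$stages` may
#' only drop trailing stages. Reruns with the same config are reproducible.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    abort("config must be created by pipeline_config()")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }
  results <- list(out_dir = config$out_dir)
  manifest <- list(config = config[setdiff(names(unclass(config)), "bp_radii")],
                   stages = list())
  stage_wrap <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage `", name, "` failed: ", conditionMessage(e)))
    })
  }

  # --- input / simulate
  truth <- NULL
  if (!is.null(config$simulate) && "simulate" %in% config$stages) {
    scene <- stage_wrap("simulate", {
      spec <- stage_preset(config$simulate, config$cultivar, seed = config$seed,
                           noise_sd = config$noise_sd,
                           outlier_frac = config$outlier_frac,
                           true_scale = config$true_scale,
                           tilt_deg = config$tilt_deg)
      generate_scene(spec)
    })
    cloud <- scene$cloud
    truth <- scene$truth
    write_cloud(cloud, file.path(config$out_dir, "scene.ply"), binary = TRUE)
    gt <- dplyr::mutate(truth$leaves, plant_height = truth$plant_height)
    write.csv(gt, file.path(config$out_dir, "ground_truth.csv"),
              row.names = FALSE)
    say("simulate: ", nrow(cloud), " points, designed height ",
        format(truth$plant_height))
    manifest$stages$simulate <- list(n_points = nrow(cloud))
  } else {
    cloud <- read_cloud(config$input)
    say("input: ", nrow(cloud), " points from ", config$input)
    manifest$stages$input <- list(n_points = nrow(cloud), path = config$input)
  }
  results$cloud <- cloud

  # --- preprocess
  if ("preprocess" %in% config$stages) {
    pre <- stage_wrap("preprocess", {
      res <- restore_scale_and_frame(
        cloud, real_width = config$real_width,
        virtual_width = config$virtual_width,
        white_thresh = config$white_thresh, dist_thresh = config$dist_thresh,
        ransac_iters = config$ransac_iters, seed = config$seed)
      ext <- extract_plant(
        res$cloud, alpha = config$alpha, eps = config$eps,
        min_size = config$min_size, voxel = config$voxel,
        dist_thresh = config$dist_thresh, ransac_iters = config$ransac_iters,
        gr_thresh = config$gr_thresh, gb_thresh = config$gb_thresh,
        sor_k = config$sor_k, sor_ratio = config$sor_ratio,
        seed = config$seed)
      list(restore = res, extract = ext)
    })
    plant_cloud <- pre$extract$cloud
    write_cloud(plant_cloud, file.path(config$out_dir, "plant.ply"),
                binary = TRUE)
    diag <- c(list(S = pre$restore$scale$s,
                   n1 = as.numeric(pre$restore$plane$normal),
                   z_threshold = pre$extract$cutoff$z_threshold),
              pre$extract$diagnostics)
    jsonlite::write_json(diag, file.path(config$out_dir, "preprocess.json"),
                         auto_unbox = TRUE, digits = NA)
    say("preprocess: S = ", format(pre$restore$scale$s), ", plant points ",
        nrow(plant_cloud), " of ", nrow(cloud))
    manifest$stages$preprocess <- diag
    results$preprocess <- pre
  } else {
    plant_cloud <- NULL
  }

  # --- segment
  seg <- NULL
  if ("segment" %in% config$stages) {
    seg <- stage_wrap("segment", region_growing(
      plant_cloud, k = config$k_geom, angle_thresh = config$angle_thresh,
      curv_thresh = config$curv_thresh, min_region = config$min_region))
    lab_cloud <- dplyr::mutate(plant_cloud, label = seg$labels)
    write.csv(lab_cloud, file.path(config$out_dir, "segmentation.csv"),
              row.names = FALSE)
    say("segment: ", seg$region_count, " regions, ",
        sum(seg$labels == -1L), " unclassified points")
    manifest$stages$segment <- list(regions = seg$region_count,
                                    unclassified = sum(seg$labels == -1L))
    results$segmentation <- seg
  }

  # --- phenotype
  phen <- NULL
  if ("phenotype" %in% config$stages) {
    phen <- stage_wrap("phenotype", phenotype_plant(
      plant_cloud, seg, crown_mode = config$crown_mode,
      surface_voxel = config$surface_voxel, leaf_voxel = config$leaf_voxel,
      stations = config$stations, span = config$span, degree = config$degree,
      bp_radii = config$bp_radii))
    write.csv(phen$plant, file.path(config$out_dir, "phenotypes_plant.csv"),
              row.names = FALSE)
    write.csv(phen$leaves, file.path(config$out_dir, "phenotypes_leaves.csv"),
              row.names = FALSE)
    say("phenotype: H = ", format(phen$plant$plant_height), " cm, ",
        nrow(phen$leaves), " leaves measured")
    manifest$stages$phenotype <- list(n_leaves = nrow(phen$leaves),
                                      failures = phen$failures)
    results$phenotypes <- phen
  }

  # --- validate (simulated scenes only)
  if ("validate" %in% config$stages && !is.null(truth) && !is.null(phen)) {
    val <- stage_wrap("validate", {
      tt <- tibble(plant_id = 1L, plant_height = truth$plant_height)
      ee <- tibble(plant_id = 1L, plant_height = phen$plant$plant_height)
      validate_traits(tt, ee, by = "plant_id")
    })
    write.csv(val$metrics, file.path(config$out_dir, "validation.csv"),
              row.names = FALSE)
    say("validate: height error ",
        format(abs(val$pairs$yhat - val$pairs$y)), " cm")
    manifest$stages$validate <- list(metrics = val$metrics)
    results$validation <- val
  }

  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  say("done: ", config$out_dir)
  invisible(results)
}
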