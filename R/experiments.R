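#' Synthetic parameter-recovery experiments
#'
#' `recovery_experiment_plants()` generates one simulated scene per seed —
#' cycling through the six growth stages (12 plants each) and the three
#' cultivar profiles, with Gaussian coordinate noise, far outliers, a random
#' global scale and a random frame tilt — runs the full restoration and
#' plant-extraction pipeline with default settings, and returns designed vs
#' extracted plant heights. `recovery_experiment_leaves()` generates one
#' standalone leaf per seed (uniform designed lengths and widths), runs
#' alignment, midrib fitting and width measurement, and returns designed vs
#' extracted leaf lengths and widths.
#'
#' @param seeds Integer seeds, one scene (or leaf) per seed.
#' @param noise_sd Coordinate noise (raw units for scenes, cm for leaves).
#' @param outlier_frac Outlier fraction for scenes.
#' @param scale_range Range of the random global scale distortion.
#' @param tilt_max Maximum frame tilt (degrees).
#' @param .progress Print one dot per scene?
#' @return A tibble with one row per seed, carrying the designed (`*_true`)
#'   and extracted (`*_extracted`) values; failed seeds carry `NA` extracted
#'   values and the error message in `error`.
#' @export
recovery_experiment_plants <- function(seeds = 1:72, noise_sd = 0.02,
                                       outlier_frac = 0.01,
                                       scale_range = c(0.3, 3), tilt_max = 15,
                                       .progress = FALSE) {
  stages <- names(stage_table)
  profiles <- c("moderate", "loose_many_tillers", "compact_few_tillers")
  rows <- lapply(seq_along(seeds), function(i) {
    sd_i <- seeds[i]
    stage <- stages[((i - 1) %/% 12) %% 6 + 1]
    profile <- profiles[(i - 1) %% 3 + 1]
    spec <- stage_preset(stage, profile, seed = sd_i)
    spec$noise_sd <- noise_sd
    spec$outlier_frac <- outlier_frac
    spec$true_scale <- runif(1, scale_range[1], scale_range[2])
    ax <- runif(1, 0, 2 * pi)
    spec$tilt_axis <- c(cos(ax), sin(ax), 0)
    spec$tilt_deg <- runif(1, 0, tilt_max)
    out <- tryCatch({
      scene <- generate_scene(spec)
      res <- restore_scale_and_frame(scene$cloud, seed = sd_i)
      ext <- extract_plant(res$cloud, seed = sd_i)
      tibble(seed = sd_i, stage = stage, cultivar = profile,
             true_scale = spec$true_scale, tilt_deg = spec$tilt_deg,
             plant_height_true = scene$truth$plant_height,
             plant_height_extracted = plant_height(ext$cloud),
             n_plant_points = nrow(ext$cloud), error = NA_character_)
    }, error = function(e) {
      tibble(seed = sd_i, stage = stage, cultivar = profile,
             true_scale = spec$true_scale, tilt_deg = spec$tilt_deg,
             plant_height_true = NA_real_, plant_height_extracted = NA_real_,
             n_plant_points = NA_integer_, error = conditionMessage(e))
    })
    if (.progress) cat(".")
    out
  })
  if (.progress) cat("\n")
  dplyr::bind_rows(rows)
}

#' @param length_range,width_range Designed leaf length and width ranges (cm).
#' @param droop_range Designed droop range.
#' @param density Leaf sampling density (points/cm^2).
#' @rdname recovery_experiment_plants
#' @export
recovery_experiment_leaves <- function(seeds = 1:160, length_range = c(5, 35),
                                       width_range = c(0.8, 2),
                                       droop_range = c(0.2, 0.9),
                                       noise_sd = 0.02, density = 150) {
  rows <- lapply(seeds, function(sd_i) {
    set.seed(sd_i)
    len <- runif(1, length_range[1], length_range[2])
    wid <- runif(1, width_range[1], width_range[2])
    dr <- runif(1, droop_range[1], droop_range[2])
    az <- runif(1, 0, 360)
    spec <- leaf_spec(length = len, max_width = wid, azimuth = az, droop = dr)
    tryCatch({
      lf <- generate_leaf(spec, density = density, noise_sd = noise_sd)
      al <- leaf_align(lf$cloud)
      mid <- fit_midrib(al$cloud)
      tibble(seed = sd_i, droop = dr,
             leaf_length_true = len, leaf_width_true = wid,
             leaf_length_extracted = leaf_length(mid),
             leaf_width_extracted = leaf_width(al$cloud, mid),
             error = NA_character_)
    }, error = function(e) {
      tibble(seed = sd_i, droop = dr,
             leaf_length_true = len, leaf_width_true = wid,
             leaf_length_extracted = NA_real_, leaf_width_extracted = NA_real_,
             error = conditionMessage(e))
    })
  })
  dplyr::bind_rows(rows)
}
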