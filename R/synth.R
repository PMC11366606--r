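#' Leaf, plant and scene specifications
#'
#' The simulator builds potted-wheat scenes from parametric specs with exact
#' ground truth. A leaf is a ribbon swept along a planar cubic Bezier midrib
#' whose shape is controlled by a single droop parameter: `droop = 0` is a
#' straight blade rising at 75 degrees, `droop = 1` arches over until the tip
#' tangent plunges at -75 degrees (the tip never falls below its attachment).
#' The control polygon is rescaled so the midrib arc length equals `length`
#' exactly (up to the 1e-7 relative error of a 2001-point quadrature). The
#' ribbon half-width follows the parabolic taper `w(t) = max_width * 4t(1-t)`,
#' clipped to `0.35 * max_width` near the base so blades do not pinch to a
#' point where they meet the sheath.
#'
#' @param length Midrib arc length (cm).
#' @param max_width Maximum blade width (cm), attained halfway along the
#'   midrib; must be smaller than `length`.
#' @param attach_height Attachment height on the tiller (cm, >= 0).
#' @param azimuth Azimuth of the leaf plane (degrees).
#' @param droop Droop parameter in `[0, 1]`.
#' @param width_profile Width profile family; only `"parabolic"` is defined.
#' @return A `leaf_spec` list.
#' @export
leaf_spec <- function(length, max_width, attach_height = 0, azimuth = 0,
                      droop = 0.5, width_profile = "parabolic") {
  if (!is.numeric(length) || length <= 0) abort("leaf length must be > 0")
  if (max_width <= 0 || max_width >= length) {
    abort("max_width must satisfy 0 < max_width < length")
  }
  if (attach_height < 0) abort("attach_height must be >= 0")
  if (droop < 0 || droop > 1) abort("droop must lie in [0, 1]")
  width_profile <- match.arg(width_profile, "parabolic")
  structure(list(length = length, max_width = max_width,
                 attach_height = attach_height, azimuth = azimuth,
                 droop = droop, width_profile = width_profile),
            class = "leaf_spec")
}

#' @param tillers Number of tillers (>= 1).
#' @param tiller_heights Stem heights (cm), one per tiller.
#' @param leaves List (one element per tiller) of lists of [leaf_spec()]s.
#' @param stem_radius Stem cylinder radius (cm).
#' @param tiller_offsets Optional `tillers x 2` matrix of basal xy offsets (cm).
#' @rdname leaf_spec
#' @export
plant_spec <- function(tillers, tiller_heights, leaves, stem_radius = 0.25,
                       tiller_offsets = NULL) {
  if (tillers < 1) abort("tillers must be >= 1")
  if (length(tiller_heights) != tillers) abort("need one tiller height per tiller")
  if (length(leaves) != tillers) abort("need one leaf list per tiller")
  if (any(tiller_heights <= 0)) abort("tiller heights must be > 0")
  if (is.null(tiller_offsets)) {
    ang <- seq(0, 2 * pi, length.out = tillers + 1)[seq_len(tillers)]
    rad <- c(0, rep(1.5, tillers - 1))
    tiller_offsets <- cbind(rad * cos(ang), rad * sin(ang))
  }
  spec <- structure(list(tillers = tillers, tiller_heights = tiller_heights,
                         leaves = leaves, stem_radius = stem_radius,
                         tiller_offsets = tiller_offsets),
                    class = "plant_spec")
  if (design_height(spec) <= 0) abort("designed plant height must be > 0")
  spec
}

#' @param plant A [plant_spec()].
#' @param pot Truncated-cone pot: list with `r_base`, `r_top`, `height` (cm).
#'   Soil sits 1 cm below the rim.
#' @param ground_extent Side length of the square ground patch (cm).
#' @param marker_width True width of the marker sticker (cm); its long side is
#'   `marker_length`.
#' @param marker_length Long side of the marker sticker (cm).
#' @param true_scale Global multiplier applied to the virtual scene (the scale
#'   distortion the preprocessing must undo).
#' @param tilt_axis,tilt_deg Axis (3-vector) and angle (degrees) of the frame
#'   tilt applied after scaling.
#' @param noise_sd Isotropic Gaussian coordinate noise (raw units) added after
#'   distortion.
#' @param outlier_count Number of far uniform outliers; if `NULL`,
#'   `outlier_frac` of the scene size.
#' @param outlier_frac Outlier fraction used when `outlier_count` is `NULL`.
#' @param densities Sampling densities in points/cm^2 per surface class:
#'   `plant`, `ground`, `pot`, `soil`, `marker`, plus `stem_factor`, the
#'   multiplier applied to `plant` for stem surfaces.
#' @param seed RNG seed.
#' @rdname leaf_spec
#' @export
scene_spec <- function(plant,
                       pot = list(r_base = 7, r_top = 9, height = 18),
                       ground_extent = 40, marker_width = 3, marker_length = 5,
                       true_scale = 1, tilt_axis = c(1, 0, 0), tilt_deg = 0,
                       noise_sd = 0, outlier_count = NULL, outlier_frac = 0,
                       densities = list(), seed = NULL) {
  stopifnot(inherits(plant, "plant_spec"))
  if (true_scale <= 0) abort("true_scale must be > 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  dens <- modifyList(list(plant = 100, stem_factor = 0.5, ground = 8, pot = 25,
                          soil = 25, marker = 250), densities)
  if (any(unlist(dens) <= 0)) abort("densities must be > 0")
  structure(list(plant = plant, pot = pot, ground_extent = ground_extent,
                 marker_width = marker_width, marker_length = marker_length,
                 true_scale = true_scale, tilt_axis = tilt_axis,
                 tilt_deg = tilt_deg, noise_sd = noise_sd,
                 outlier_count = outlier_count, outlier_frac = outlier_frac,
                 densities = dens, seed = seed),
            class = "scene_spec")
}

# ------------------------------------------------------------- midrib curve

# discretized planar midrib (unit control polygon, in-plane coords s/z)
midrib_curve_2d <- function(droop, n = 2001) {
  th0 <- 75 * pi / 180
  thB <- (75 - 75 * droop) * pi / 180
  tht <- (75 - 150 * droop) * pi / 180
  p0 <- c(0, 0)
  p1 <- 0.33 * c(cos(th0), sin(th0))
  p3 <- c(cos(thB), sin(thB))
  p2 <- p3 - 0.33 * c(cos(tht), sin(tht))
  t <- seq(0, 1, length.out = n)
  b0 <- (1 - t)^3; b1 <- 3 * t * (1 - t)^2; b2 <- 3 * t^2 * (1 - t); b3 <- t^3
  s <- b0 * p0[1] + b1 * p1[1] + b2 * p2[1] + b3 * p3[1]
  z <- b0 * p0[2] + b1 * p1[2] + b2 * p2[2] + b3 * p3[2]
  arc <- c(0, cumsum(sqrt(diff(s)^2 + diff(z)^2)))
  list(s = s, z = z, arc = arc)
}

# parabolic taper clipped near the base; t is arc-length fraction in [0, 1]
leaf_width_profile <- function(t, max_width) {
  max_width * pmax(4 * t * (1 - t), 0.35 * (t < 0.5))
}

# apex rise (max midrib z, per unit arc length) for a droop value
leaf_apex_rise <- function(droop) {
  cv <- midrib_curve_2d(droop, n = 501)
  max(cv$z) / max(cv$arc)
}

# designed plant height: tallest of tiller tips and leaf apices, stem base at 0
design_height <- function(plant) {
  apex <- 0
  for (ti in seq_len(plant$tillers)) {
    for (lf in plant$leaves[[ti]]) {
      cv <- midrib_curve_2d(lf$droop)
      apex <- max(apex, lf$attach_height + max(cv$z) * lf$length / max(cv$arc))
    }
  }
  max(max(plant$tiller_heights), apex)
}

clip255 <- function(v) as.integer(pmin(255, pmax(0, round(v))))

# clipped-Gaussian RGB sampler; `side` enforces the color-filter contract by
# resampling: plant colors always satisfy both margins (G-R > 5, G-B > 30),
# non-plant scene colors always violate at least one
class_colors <- function(n, mean, sd, side = c("none", "plant", "nonplant"),
                         gr = 5, gb = 30) {
  side <- match.arg(side)
  draw <- function(m) cbind(clip255(rnorm(m, mean[1], sd)),
                            clip255(rnorm(m, mean[2], sd)),
                            clip255(rnorm(m, mean[3], sd)))
  out <- draw(n)
  if (side != "none") {
    ok_fun <- function(cc) {
      pass <- (cc[, 2] - cc[, 1]) > gr & (cc[, 2] - cc[, 3]) > gb
      if (side == "plant") pass else !pass
    }
    for (it in 1:100) {
      bad <- which(!ok_fun(out))
      if (!length(bad)) break
      out[bad, ] <- draw(length(bad))
    }
    bad <- which(!ok_fun(out))
    if (length(bad)) {  # deterministic fallback after resampling
      if (side == "plant") {
        out[bad, ] <- matrix(rep(c(60, 140, 60), each = length(bad)),
                             ncol = 3)
      } else {
        out[bad, 2] <- pmax(0L, out[bad, 3] + 25L)
      }
    }
  }
  out
}

plant_green <- function(n) class_colors(n, c(60, 140, 60), 12, "plant")

# ------------------------------------------------------------ leaf sampling

#' Sample a synthetic leaf ribbon
#'
#' Draws points uniformly on the ribbon surface of a [leaf_spec()] (area
#' density `density`), anchored at `base_xy` with its attachment at
#' `attach_height`. The true midrib polyline and designed width are returned
#' alongside, and the base, tip and apex midrib points are always included as
#' exact samples.
#'
#' @param spec A [leaf_spec()].
#' @param density Sampling density (points/cm^2).
#' @param noise_sd Isotropic Gaussian noise added to the sampled points (cm).
#' @param seed Optional RNG seed.
#' @param base_xy Attachment position in the xy plane (cm).
#' @param colored Attach wheat-green RGB columns?
#' @return A list with `cloud` (point tibble), `midrib` (200-point polyline
#'   tibble, noiseless truth), `length` and `width` (the designed values).
#' @export
generate_leaf <- function(spec, density = 150, noise_sd = 0, seed = NULL,
                          base_xy = c(0, 0), colored = TRUE) {
  stopifnot(inherits(spec, "leaf_spec"))
  if (!is.null(seed)) set.seed(seed)
  cv <- midrib_curve_2d(spec$droop)
  sc <- spec$length / max(cv$arc)
  arc <- cv$arc * sc                     # 0 .. length
  tfrac <- arc / spec$length
  area <- spec$length * mean(leaf_width_profile(tfrac, spec$max_width))
  n <- round(density * area)
  if (n < 50) abort("density too low: expected fewer than 50 leaf points")
  s_par <- runif(n, 0, spec$length)
  # deterministic extremes: base, tip, apex of the midrib
  i_apex <- which.max(cv$z)
  s_det <- c(0, spec$length, arc[i_apex])
  v_det <- c(0, 0, 0)
  t_all <- c(s_par, s_det) / spec$length
  w <- leaf_width_profile(t_all, spec$max_width)
  v <- c(runif(n, -0.5, 0.5) * w[seq_len(n)], v_det)
  sx <- approx(arc, cv$s * sc, xout = c(s_par, s_det), rule = 2)$y
  sz <- approx(arc, cv$z * sc, xout = c(s_par, s_det), rule = 2)$y
  phi <- spec$azimuth * pi / 180
  d <- c(cos(phi), sin(phi))
  u <- c(-sin(phi), cos(phi))
  pts <- cbind(base_xy[1] + sx * d[1] + v * u[1],
               base_xy[2] + sx * d[2] + v * u[2],
               spec$attach_height + sz)
  if (noise_sd > 0) pts <- pts + matrix(rnorm(length(pts), 0, noise_sd), ncol = 3)
  cl <- tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3])
  if (colored) {
    col <- plant_green(nrow(cl))
    cl$r <- col[, 1]; cl$g <- col[, 2]; cl$b <- col[, 3]
  }
  mid_s <- seq(0, spec$length, length.out = 200)
  mx <- approx(arc, cv$s * sc, xout = mid_s, rule = 2)$y
  mz <- approx(arc, cv$z * sc, xout = mid_s, rule = 2)$y
  midrib <- tibble(x = base_xy[1] + mx * d[1], y = base_xy[2] + mx * d[2],
                   z = spec$attach_height + mz)
  list(cloud = cl, midrib = midrib, length = spec$length, width = spec$max_width)
}

# ----------------------------------------------------------- scene assembly

sample_disc <- function(n, radius, centre = c(0, 0)) {
  r <- radius * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  cbind(centre[1] + r * cos(a), centre[2] + r * sin(a))
}

rotation_axis_angle <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a raw wheat scene with ground truth
#'
#' Assembles the canonical upright scene (plant in a soil-filled pot on a
#' planar ground patch, with a white marker sticker of known width on the pot
#' wall), records the ground truth, then applies the scale and tilt
#' distortions, Gaussian coordinate noise and uniform far outliers that a raw
#' multi-view-stereo reconstruction exhibits. Plant points are wheat green and
#' exceed the G-R > 5 and G-B > 30 margins by construction; soil, pot and
#' marker colors violate at least one margin.
#'
#' @param spec A [scene_spec()].
#' @return A list with `cloud` (the distorted colored scene tibble), `truth`
#'   (class labels, designed plant height, per-leaf table and memberships,
#'   true midribs, the noiseless canonical coordinates, scale and tilt), and
#'   `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  dens <- spec$densities
  pot <- spec$pot
  soil_z <- pot$height - 1
  plant <- spec$plant

  pts <- list(); cols <- list(); labs <- list(); leaf_id <- list()
  midribs <- list(); leaf_rows <- list()

  # plant: stems and leaves, stem bases at soil level
  stem_dens <- dens$plant * dens$stem_factor
  kleaf <- 0L
  for (ti in seq_len(plant$tillers)) {
    off <- plant$tiller_offsets[ti, ]
    h <- plant$tiller_heights[ti]
    ns <- max(20L, round(2 * pi * plant$stem_radius * h * stem_dens))
    a <- runif(ns, 0, 2 * pi)
    zz <- runif(ns, 0, h)
    sp <- cbind(off[1] + plant$stem_radius * cos(a),
                off[2] + plant$stem_radius * sin(a), soil_z + zz)
    # exact base and tip samples pin the designed height
    sp <- rbind(sp, c(off[1] + plant$stem_radius, off[2], soil_z),
                c(off[1], off[2], soil_z + h))
    pts[[length(pts) + 1L]] <- sp
    cols[[length(cols) + 1L]] <- plant_green(nrow(sp))
    labs[[length(labs) + 1L]] <- rep("plant", nrow(sp))
    leaf_id[[length(leaf_id) + 1L]] <- rep(0L, nrow(sp))
    for (lf in plant$leaves[[ti]]) {
      kleaf <- kleaf + 1L
      lf_at <- lf
      lf_at$attach_height <- soil_z + lf$attach_height
      # blades emerge at the stem surface, not the stem axis
      phi <- lf$azimuth * pi / 180
      base_xy <- off + (plant$stem_radius + 0.05) * c(cos(phi), sin(phi))
      gl <- generate_leaf(lf_at, density = dens$plant, base_xy = base_xy,
                          colored = TRUE)
      pts[[length(pts) + 1L]] <- cloud_matrix(gl$cloud)
      cols[[length(cols) + 1L]] <- cloud_colors(gl$cloud)
      labs[[length(labs) + 1L]] <- rep("plant", nrow(gl$cloud))
      leaf_id[[length(leaf_id) + 1L]] <- rep(kleaf, nrow(gl$cloud))
      midribs[[kleaf]] <- gl$midrib
      leaf_rows[[kleaf]] <- tibble(leaf_id = kleaf, tiller = ti,
                                   length = lf$length, max_width = lf$max_width,
                                   attach_height = lf$attach_height,
                                   azimuth = lf$azimuth, droop = lf$droop)
    }
  }

  # pot lateral surface (truncated cone, axis z)
  slant <- sqrt((pot$r_top - pot$r_base)^2 + pot$height^2)
  npot <- round(pi * (pot$r_base + pot$r_top) * slant * dens$pot)
  # z density proportional to local radius
  zq <- runif(npot)
  r0 <- pot$r_base; r1 <- pot$r_top
  zz <- if (abs(r1 - r0) < 1e-12) zq * pot$height else
    pot$height * (sqrt(r0^2 + zq * (r1^2 - r0^2)) - r0) / (r1 - r0)
  rr <- r0 + (r1 - r0) * zz / pot$height
  aa <- runif(npot, 0, 2 * pi)
  pp <- cbind(rr * cos(aa), rr * sin(aa), zz)
  pts[[length(pts) + 1L]] <- pp
  cols[[length(cols) + 1L]] <- class_colors(npot, c(150, 60, 50), 10, "nonplant")
  labs[[length(labs) + 1L]] <- rep("pot", npot)
  leaf_id[[length(leaf_id) + 1L]] <- rep(NA_integer_, npot)

  # soil surface inside the pot
  r_soil <- r0 + (r1 - r0) * soil_z / pot$height
  nsoil <- round(pi * r_soil^2 * dens$soil)
  sxy <- sample_disc(nsoil, r_soil)
  pts[[length(pts) + 1L]] <- cbind(sxy, soil_z)
  cols[[length(cols) + 1L]] <- class_colors(nsoil, c(120, 100, 80), 10, "nonplant")
  labs[[length(labs) + 1L]] <- rep("soil", nsoil)
  leaf_id[[length(leaf_id) + 1L]] <- rep(NA_integer_, nsoil)

  # planar ground patch around the pot
  g <- spec$ground_extent
  ng <- round(g^2 * dens$ground)
  gx <- runif(ng, -g / 2, g / 2); gy <- runif(ng, -g / 2, g / 2)
  keep <- gx^2 + gy^2 > r0^2
  gx <- gx[keep]; gy <- gy[keep]
  ngk <- length(gx)
  pts[[length(pts) + 1L]] <- cbind(gx, gy, 0)
  cols[[length(cols) + 1L]] <- class_colors(ngk, c(110, 105, 95), 10, "nonplant")
  labs[[length(labs) + 1L]] <- rep("ground", ngk)
  leaf_id[[length(leaf_id) + 1L]] <- rep(NA_integer_, ngk)

  # marker sticker: planar patch tangent to the pot wall, exact designed width
  zc <- 0.6 * pot$height
  rc <- r0 + (r1 - r0) * zc / pot$height
  nm <- round(spec$marker_width * spec$marker_length * dens$marker)
  th_h <- c(0, 1, 0)                                  # horizontal tangent
  tv <- c((r1 - r0) / slant, 0, pot$height / slant)   # up-slope direction
  am <- runif(nm, -0.5, 0.5) * spec$marker_length
  bm <- runif(nm, -0.5, 0.5) * spec$marker_width
  centre <- c(rc + 0.05, 0, zc)
  mp <- cbind(centre[1] + am * th_h[1] + bm * tv[1],
              centre[2] + am * th_h[2] + bm * tv[2],
              centre[3] + am * th_h[3] + bm * tv[3])
  pts[[length(pts) + 1L]] <- mp
  cols[[length(cols) + 1L]] <- class_colors(nm, c(250, 250, 250), 5, "nonplant")
  labs[[length(labs) + 1L]] <- rep("marker", nm)
  leaf_id[[length(leaf_id) + 1L]] <- rep(NA_integer_, nm)

  canonical <- do.call(rbind, pts)
  col_all <- do.call(rbind, cols)
  lab_all <- do.call(c, labs)
  leaf_all <- do.call(c, leaf_id)
  n_scene <- nrow(canonical)

  # distortion: scale, then tilt
  R <- rotation_axis_angle(spec$tilt_axis, spec$tilt_deg)
  raw <- (canonical * spec$true_scale) %*% t(R)
  if (spec$noise_sd > 0) {
    raw <- raw + matrix(rnorm(length(raw), 0, spec$noise_sd), ncol = 3)
  }

  n_out <- spec$outlier_count %||% round(spec$outlier_frac * n_scene)
  if (n_out > 0) {
    lo <- apply(raw, 2, min); hi <- apply(raw, 2, max)
    mid <- (lo + hi) / 2; half <- (hi - lo) / 2 * 3
    op <- cbind(runif(n_out, mid[1] - half[1], mid[1] + half[1]),
                runif(n_out, mid[2] - half[2], mid[2] + half[2]),
                runif(n_out, mid[3] - half[3], mid[3] + half[3]))
    raw <- rbind(raw, op)
    col_all <- rbind(col_all, cbind(sample.int(256, n_out, TRUE) - 1L,
                                    sample.int(256, n_out, TRUE) - 1L,
                                    sample.int(256, n_out, TRUE) - 1L))
    lab_all <- c(lab_all, rep("outlier", n_out))
    leaf_all <- c(leaf_all, rep(NA_integer_, n_out))
  }

  cloud <- tibble(x = raw[, 1], y = raw[, 2], z = raw[, 3],
                  r = as.integer(col_all[, 1]), g = as.integer(col_all[, 2]),
                  b = as.integer(col_all[, 3]))
  truth <- structure(list(
    label = lab_all,
    leaf_id = leaf_all,
    plant_height = design_height(plant),
    leaves = if (kleaf > 0) dplyr::bind_rows(leaf_rows) else tibble(),
    midribs = midribs,
    canonical = canonical,
    soil_z = soil_z,
    true_scale = spec$true_scale,
    tilt = R
  ), class = "scene_truth")
  list(cloud = cloud, truth = truth, spec = spec)
}

# ------------------------------------------------------------ stage presets

stage_table <- list(
  seedling      = list(h = c(10, 13), tillers = 1, leaves = 3,
                       len = c(5, 9),   wid = c(0.35, 0.6), droop = c(0.25, 0.5)),
  tillering     = list(h = c(15, 20), tillers = 3, leaves = 3,
                       len = c(8, 14),  wid = c(0.5, 0.8),  droop = c(0.3, 0.6)),
  jointing      = list(h = c(25, 33), tillers = 5, leaves = 4,
                       len = c(12, 20), wid = c(0.7, 1.1),  droop = c(0.3, 0.7)),
  booting       = list(h = c(36, 44), tillers = 6, leaves = 4,
                       len = c(15, 24), wid = c(0.9, 1.4),  droop = c(0.35, 0.75)),
  heading       = list(h = c(46, 53), tillers = 7, leaves = 4,
                       len = c(16, 26), wid = c(1.0, 1.6),  droop = c(0.4, 0.8)),
  grain_filling = list(h = c(54, 60), tillers = 8, leaves = 4,
                       len = c(16, 28), wid = c(1.0, 1.8),  droop = c(0.5, 0.9))
)

#' Stage presets for scene simulation
#'
#' Returns a [scene_spec()] with stage-appropriate tiller counts, stem heights
#' and leaf sizes for the six wheat growth stages, modulated by a cultivar
#' architecture profile. The designed plant height is drawn from
#' non-overlapping, increasing per-stage ranges (using a shared uniform draw
#' per seed, so heights are monotone across stages for a fixed seed), and leaf
#' attachment heights and lengths are capped so that no leaf apex overtops the
#' tallest stem; the designed height therefore equals the drawn stem height
#' exactly. Parameter ranges are simulator choices, not field measurements.
#'
#' @param stage Growth stage name.
#' @param cultivar_profile Plant architecture: `"moderate"`,
#'   `"loose_many_tillers"` (two extra tillers, droopier and wider spread) or
#'   `"compact_few_tillers"` (one fewer tiller, slightly shorter).
#' @param seed RNG seed (deterministic preset per seed).
#' @param ... Overrides passed on to [scene_spec()] (e.g. `noise_sd`,
#'   `true_scale`, `tilt_deg`, `outlier_frac`).
#' @return A [scene_spec()].
#' @export
stage_preset <- function(stage = c("seedling", "tillering", "jointing",
                                   "booting", "heading", "grain_filling"),
                         cultivar_profile = c("moderate", "loose_many_tillers",
                                              "compact_few_tillers"),
                         seed = NULL, ...) {
  stage <- match.arg(stage)
  cultivar_profile <- match.arg(cultivar_profile)
  if (!is.null(seed)) set.seed(seed)
  st <- stage_table[[stage]]
  u <- runif(1)
  h_star <- st$h[1] + u * diff(st$h)
  tillers <- st$tillers
  droop_shift <- 0
  az_jitter <- 40
  if (cultivar_profile == "loose_many_tillers") {
    tillers <- tillers + 2L
    droop_shift <- 0.05
    az_jitter <- 70
  } else if (cultivar_profile == "compact_few_tillers") {
    tillers <- max(1L, tillers - 1L)
    h_star <- h_star * 0.97
    az_jitter <- 25
  }
  heights <- c(h_star, h_star * runif(tillers - 1, 0.75, 0.95))
  golden <- 137.5
  leaves <- vector("list", tillers)
  kk <- 0
  for (ti in seq_len(tillers)) {
    nl <- st$leaves
    fr <- seq(0.25, 0.8, length.out = nl) * heights[ti]
    ll <- vector("list", nl)
    for (j in seq_len(nl)) {
      kk <- kk + 1
      dr <- min(1, runif(1, st$droop[1], st$droop[2]) + droop_shift)
      len <- runif(1, st$len[1], st$len[2])
      att <- fr[j] * runif(1, 0.9, 1.05)
      att <- min(att, heights[ti] * 0.85)
      # the leaf apex must not overtop the tallest stem: lower the attachment
      # first, and only shorten the blade if that is not enough
      rise <- leaf_apex_rise(dr)
      att <- min(att, max(0.15 * heights[ti], h_star - rise * len))
      len <- min(len, max(4, (h_star - att) / rise))
      wid <- min(runif(1, st$wid[1], st$wid[2]), 0.45 * len)
      az <- (kk * golden + runif(1, -az_jitter, az_jitter)) %% 360
      ll[[j]] <- leaf_spec(length = len, max_width = wid, attach_height = att,
                           azimuth = az, droop = dr)
    }
    leaves[[ti]] <- ll
  }
  plant <- plant_spec(tillers, heights, leaves)
  args <- modifyList(list(noise_sd = 0.02, outlier_frac = 0.01), list(...))
  do.call(scene_spec, c(list(plant = plant), args))
}
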