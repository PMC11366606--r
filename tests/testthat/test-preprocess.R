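test_that("scale estimation is the mean-ratio of Eq. 1", {
  expect_equal(estimate_scale(c(1.5, 1.5, 1.5), 3)$s, 2)
  expect_equal(estimate_scale(c(3, 3, 3), 3)$s, 1)
  expect_equal(estimate_scale(c(2.9, 3.0, 3.1), 3)$s, 1)
  expect_error(estimate_scale(c(1, -1), 3), "positive")
})

test_that("marker width is the minor-axis extent of the patch", {
  set.seed(1)
  patch <- tibble::tibble(x = runif(800, 0, 3), y = runif(800, 0, 1), z = 0)
  expect_equal(measure_marker_width(patch, marker_mask = rep(TRUE, 800),
                                    cluster = FALSE, seed = 1),
               1, tolerance = 0.05)
  half <- apply_scale(patch, 0.5)
  expect_equal(measure_marker_width(half, marker_mask = rep(TRUE, 800),
                                    cluster = FALSE, seed = 1),
               0.5, tolerance = 0.03)
  noisy <- patch
  noisy$z <- rnorm(800, 0, 0.02)
  expect_equal(measure_marker_width(noisy, marker_mask = rep(TRUE, 800),
                                    cluster = FALSE, seed = 1),
               1, tolerance = 0.05)
  expect_error(measure_marker_width(patch[1:5, ], marker_mask = rep(TRUE, 5)),
               "manually")
})

test_that("apply_scale multiplies coordinates and pairwise distances", {
  cl <- as_cloud(rbind(c(1, 2, 3)))
  expect_equal(unlist(apply_scale(cl, 2)[1, ]), c(x = 2, y = 4, z = 6))
  expect_identical(apply_scale(cl, 1), cl)
  set.seed(2)
  rc <- as_cloud(matrix(rnorm(60), ncol = 3))
  expect_equal(as.matrix(dist(cloud_coords(apply_scale(rc, 3.7)))),
               3.7 * as.matrix(dist(cloud_coords(rc))), tolerance = 1e-12)
})

test_that("RANSAC recovers planes despite outliers", {
  set.seed(3)
  flat <- tibble::tibble(x = runif(1000, -5, 5), y = runif(1000, -5, 5), z = 0)
  junk <- tibble::tibble(x = runif(10, -5, 5), y = runif(10, -5, 5),
                         z = runif(10, 1, 10))
  pm <- fit_ground_plane(dplyr::bind_rows(flat, junk), dist_thresh = 0.05,
                         seed = 1)
  expect_lt(max(abs(abs(pm$normal) - c(0, 0, 1))), 1e-6)
  expect_gte(length(pm$inlier_indices), 1000)

  # 10-degree incline
  x <- runif(2000, -5, 5); y <- runif(2000, -5, 5)
  tilted <- tibble::tibble(x = x, y = y, z = x * tan(10 * pi / 180))
  pm2 <- fit_ground_plane(tilted, dist_thresh = 0.05, seed = 1)
  truth <- c(-sin(10 * pi / 180), 0, cos(10 * pi / 180))
  ang <- acos(min(1, abs(sum(pm2$normal * truth)))) * 180 / pi
  expect_lt(ang, 0.1)
})

test_that("with two equal parallel planes one plane's population wins", {
  set.seed(4)
  mk <- function(z0) tibble::tibble(x = runif(500, -5, 5),
                                    y = runif(500, -5, 5), z = z0)
  pm <- fit_ground_plane(dplyr::bind_rows(mk(0), mk(5)), dist_thresh = 0.05,
                         seed = 7)
  expect_equal(length(pm$inlier_indices), 500)
  # deterministic given the seed
  pm2 <- fit_ground_plane(dplyr::bind_rows(mk(0), mk(5)), dist_thresh = 0.05,
                          seed = 7)
  expect_identical(pm$offset, pm2$offset)
  expect_error(fit_ground_plane(as_cloud(cbind(1:5, 1:5, 1:5)),
                                dist_thresh = 1e-6, seed = 1),
               "degenerate|collinear")
})

test_that("rotation_to_reference maps n1 onto the reference axis", {
  expect_equal(rotation_to_reference(c(0, 0, 1)), diag(3))
  R <- rotation_to_reference(c(1, 0, 0))
  expect_equal(as.vector(R %*% c(1, 0, 0)), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  # antiparallel: rotation by pi about the fallback axis (1, 0, 0)
  R2 <- rotation_to_reference(c(0, 0, -1))
  expect_equal(as.vector(R2 %*% c(0, 0, -1)), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(as.vector(R2 %*% c(1, 0, 0)), c(1, 0, 0), tolerance = 1e-12)
})

test_that("rotation_to_reference yields proper rotations for random normals", {
  set.seed(5)
  for (i in 1:50) {
    n1 <- random_unit()
    R <- rotation_to_reference(n1)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_lt(max(abs(R %*% n1 - c(0, 0, 1))), 1e-9)
  }
})

test_that("apply_rotation is an isometry and levels tilted scenes", {
  set.seed(6)
  cl <- as_cloud(matrix(rnorm(300), ncol = 3))
  expect_equal(apply_rotation(cl, diag(3)), cl)
  R <- rotation_to_reference(random_unit())
  expect_equal(sqrt(rowSums(cloud_coords(apply_rotation(cl, R))^2)),
               sqrt(rowSums(cloud_coords(cl)^2)), tolerance = 1e-12)

  spec <- stage_preset("seedling", "moderate", seed = 12, true_scale = 1,
                       tilt_deg = 14, noise_sd = 0.02, outlier_frac = 0)
  sc <- generate_scene(spec)
  res <- restore_scale_and_frame(sc$cloud, virtual_width = 3, seed = 12)
  ground <- res$cloud$z[sc$truth$label == "ground"]
  expect_lt(sd(ground), 0.2)
  expect_lt(abs(mean(ground)), 0.05)
})

test_that("color filtering uses strict margins", {
  cl <- tibble::tibble(x = 0, y = 0, z = 0,
                       r = c(10L, 100L, 95L), g = c(120L, 100L, 100L),
                       b = c(30L, 100L, 70L))
  expect_equal(color_filter(cl), c(TRUE, FALSE, FALSE))
  expect_error(color_filter(cl[, 1:3]), "color")
  h <- color_margin_histogram(cl)
  expect_equal(sum(h$count[h$margin == "G-R"]), 3)
  expect_equal(sum(h$count[h$margin == "G-B"]), 3)
})

test_that("statistical outlier removal matches the O(N^2) oracle", {
  g <- expand.grid(x = 0:9, y = 0:9, z = 0)
  grid <- tibble::tibble(x = as.numeric(g$x), y = as.numeric(g$y),
                         z = as.numeric(g$z))
  far <- dplyr::bind_rows(grid, tibble::tibble(x = 100, y = 100, z = 100))
  mask <- statistical_outlier_removal(far, k = 8, std_ratio = 2)
  expect_false(mask[101])
  expect_identical(mask, bf_sor_mask(cloud_coords(far), 8, 2))

  # grid alone: kd-tree path equals brute force; interior points all survive
  m2 <- statistical_outlier_removal(grid, k = 8, std_ratio = 2)
  expect_identical(m2, bf_sor_mask(cloud_coords(grid), 8, 2))
  interior <- g$x %in% 1:8 & g$y %in% 1:8
  expect_true(all(m2[interior]))

  set.seed(7)
  rc <- as_cloud(matrix(rnorm(1500), ncol = 3))
  expect_identical(statistical_outlier_removal(rc, k = 12, std_ratio = 1.5),
                   bf_sor_mask(cloud_coords(rc), 12, 1.5))
  expect_error(statistical_outlier_removal(rc[1:5, ], k = 10), "more points")
})

test_that("voxel downsampling averages voxel members", {
  cl <- as_cloud(rbind(c(0.01, 0.01, 0.01), c(0.02, 0.02, 0.02)))
  out <- voxel_downsample(cl, 0.1)
  expect_equal(nrow(out), 1)
  expect_equal(unlist(out[1, ]), c(x = 0.015, y = 0.015, z = 0.015))

  set.seed(8)
  rc <- as_cloud(matrix(runif(900, 0, 10), ncol = 3))
  # voxel below min spacing: identity up to ordering
  tiny <- voxel_downsample(rc, 1e-4)
  expect_equal(nrow(tiny), nrow(rc))
  expect_setequal(round(tiny$x, 9), round(rc$x, 9))
  # occupied voxel count equals an independent grid hash
  vox <- voxel_downsample(rc, 0.7)
  key <- paste(floor(rc$x / 0.7), floor(rc$y / 0.7), floor(rc$z / 0.7))
  expect_equal(nrow(vox), length(unique(key)))
})

test_that("euclidean clustering equals proximity-graph components", {
  line <- as_cloud(cbind(seq(0, 5, by = 0.5), 0, 0))
  expect_true(all(euclidean_cluster(line, 0.6) == 1))
  expect_equal(max(euclidean_cluster(line, 0.4, min_size = 1)), nrow(line))

  set.seed(9)
  rc <- as_cloud(matrix(runif(900, 0, 5), ncol = 3))
  lab <- euclidean_cluster(rc, 0.45, min_size = 1)
  expect_true(same_partition(lab, bf_components(cloud_coords(rc), 0.45)))

  # permutation invariance (up to relabelling)
  perm <- sample(nrow(rc))
  lab2 <- euclidean_cluster(rc[perm, ], 0.45, min_size = 1)
  expect_true(same_partition(lab2, lab[perm]))
})

test_that("the centroid cutoff follows Eq. 5 exactly", {
  expect_equal(cutoff_threshold(2, 12, 0.3)$z_threshold, 5)
  expect_equal(cutoff_threshold(2, 12, 0)$z_threshold, 2)
  expect_equal(cutoff_threshold(2, 12, 1)$z_threshold, 12)
  expect_error(cutoff_threshold(0, 1, 1.5), "alpha")
})

test_that("plant extraction is precise and complete on noiseless scenes", {
  sc <- quiet_scene(seed = 5)
  ext <- extract_plant(sc$cloud, seed = 5)
  kept <- rep(FALSE, nrow(sc$cloud))
  kept[ext$indices] <- TRUE
  is_plant <- sc$truth$label == "plant"
  expect_gte(sum(kept & is_plant) / sum(is_plant), 0.99)
  expect_gte(sum(kept & is_plant) / sum(kept), 0.99)
  expect_equal(ext$cutoff$z_threshold,
               ext$cutoff$z_ground +
                 0.3 * (ext$cutoff$z_plant - ext$cutoff$z_ground))

  nogreen <- sc$cloud[sc$truth$label == "ground", ]
  expect_error(extract_plant(nogreen, seed = 1), "plant-colored")
})

test_that("lowering alpha never discards plant points kept at higher alpha", {
  sc <- quiet_scene(seed = 7)
  is_plant <- sc$truth$label == "plant"
  kept_prev <- NULL
  for (alpha in c(0.3, 0.15, 0.05)) {
    ext <- extract_plant(sc$cloud, alpha = alpha, seed = 7)
    kept <- intersect(ext$indices, which(is_plant))
    if (!is.null(kept_prev)) expect_true(all(kept_prev %in% kept))
    kept_prev <- kept
  }
})

test_that("marker-based restoration recovers the true scale", {
  spec <- stage_preset("tillering", "moderate", seed = 13, true_scale = 0.5,
                       tilt_deg = 8, noise_sd = 0.02, outlier_frac = 0.01)
  sc <- generate_scene(spec)
  res <- restore_scale_and_frame(sc$cloud, seed = 13)
  # restored marker width = 3 cm within 2 * noise_sd
  m <- apply_scale(sc$cloud[sc$truth$label == "marker", ], res$scale$s)
  w <- measure_marker_width(m, marker_mask = rep(TRUE, nrow(m)),
                            cluster = FALSE, seed = 1)
  expect_lt(abs(w - 3), 2 * 0.02 / 0.5)
  expect_equal(res$scale$s * 0.5, 1, tolerance = 0.03)
})
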