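#' Scale restoration from a marker of known width
#'
#' Multi-view-stereo reconstructions come out in an arbitrary metric scale.
#' The scale factor is `S = W_real / W_virtual`, where `W_virtual` is the
#' mean of repeated width measurements of a marker sticker in the cloud and
#' `W_real` its physical width (3 cm by default).
#'
#' @param width_measurements Positive width measurements in cloud units
#'   (typically three repeats).
#' @param real_width True marker width (cm).
#' @return A `scale_estimate` list with `w_virtual`, `w_real` and `s`.
#' @examples
#' estimate_scale(c(1.5, 1.5, 1.5), 3) # S = 2
#' @export
estimate_scale <- function(width_measurements, real_width = 3) {
  if (!length(width_measurements) || any(width_measurements <= 0)) {
    abort("width measurements must be positive")
  }
  if (real_width <= 0) abort("real_width must be > 0")
  w <- mean(width_measurements)
  structure(list(w_virtual = w, w_real = real_width, s = real_width / w),
            class = "scale_estimate")
}

#' @export
print.scale_estimate <- function(x, ...) {
  cat(sprintf("<scale_estimate> W_virtual = %.4g, W_real = %.4g, S = %.6g\n",
              x$w_virtual, x$w_real, x$s))
  invisible(x)
}

#' Automated marker width measurement
#'
#' Selects the marker patch (by default: near-white points, tightened to the
#' largest Euclidean cluster so white-ish far outliers cannot corrupt the
#' fit), projects it on its second principal axis and estimates the extent of
#' the projections. The extent is taken as the trimmed-quantile estimator
#' `(q95 - q05) / 0.90`, which is unbiased for a uniform strip and, unlike the
#' raw min-max range, is not inflated by boundary noise; the returned value is
#' the mean of three bootstrap re-measurements.
#'
#' @param cloud A colored point-cloud tibble (or any cloud if `marker_mask`
#'   is given).
#' @param marker_mask Optional logical mask or integer indices selecting the
#'   marker points; by default points with all RGB channels > `white_thresh`.
#' @param white_thresh Whiteness threshold for the default selector.
#' @param cluster Keep only the largest Euclidean cluster of the selection?
#' @param seed Optional seed for the bootstrap repeats.
#' @return The measured width, in the units of `cloud`.
#' @export
measure_marker_width <- function(cloud, marker_mask = NULL, white_thresh = 200,
                                 cluster = TRUE, seed = NULL) {
  validate_cloud(cloud)
  if (is.null(marker_mask)) {
    validate_cloud(cloud, colors = TRUE)
    marker_mask <- cloud$r > white_thresh & cloud$g > white_thresh &
      cloud$b > white_thresh
  }
  sub <- cloud[marker_mask, , drop = FALSE]
  if (nrow(sub) >= 20 && cluster) {
    P <- cloud_matrix(sub)
    spacing <- mean(.cpp_knn(P, 1)$dist)
    lab <- .cpp_euclidean_cluster(P, 3 * spacing, 1L)
    keep <- lab == as.integer(names(which.max(table(lab[lab > 0]))))
    sub <- sub[keep, , drop = FALSE]
  }
  if (nrow(sub) < 20) {
    abort("fewer than 20 marker points selected; measure the marker manually and pass `virtual_width`")
  }
  if (!is.null(seed)) set.seed(seed)
  P <- cloud_matrix(sub)
  one <- function(idx) {
    Q <- P[idx, , drop = FALSE]
    pc <- prcomp(Q, center = TRUE, scale. = FALSE)
    proj <- pc$x[, 2]
    unname(diff(quantile(proj, c(0.05, 0.95), names = FALSE, type = 7)) / 0.90)
  }
  reps <- vapply(1:3, function(i) one(sample.int(nrow(P), replace = TRUE)), 0)
  mean(reps)
}

#' Apply a scale factor or a rotation to a cloud
#'
#' @param cloud A point-cloud tibble.
#' @param s Positive scale factor.
#' @return The transformed cloud (colors and extra columns untouched).
#' @export
apply_scale <- function(cloud, s) {
  validate_cloud(cloud)
  if (!is.numeric(s) || s <= 0) abort("scale must be > 0")
  cloud$x <- cloud$x * s
  cloud$y <- cloud$y * s
  cloud$z <- cloud$z * s
  cloud
}

#' @param R A 3x3 proper rotation matrix.
#' @rdname apply_scale
#' @export
apply_rotation <- function(cloud, R) {
  validate_cloud(cloud)
  check_rotation(R)
  set_coords(cloud, cloud_matrix(cloud) %*% t(R))
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3))) abort("R must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    abort("R is not a proper rotation matrix")
  }
  invisible(R)
}

#' Similarity transform (scale + rotation)
#'
#' @param s Positive scale factor.
#' @param R 3x3 proper rotation.
#' @param z_offset Vertical translation applied after rotation (ground-to-zero
#'   convention).
#' @export
similarity_transform <- function(s, R = diag(3), z_offset = 0) {
  if (s <= 0) abort("S must be > 0")
  check_rotation(R, tol = 1e-9)
  structure(list(s = s, R = R, z_offset = z_offset),
            class = "similarity_transform")
}

#' RANSAC ground-plane fit
#'
#' Repeatedly samples point triples, keeps the plane supporting the most
#' points within `dist_thresh`, and refines it by total least squares on the
#' inliers (centroid + smallest covariance eigenvector). The normal is
#' oriented so that the plant side (the centroid of green points when colors
#' are available, otherwise of the whole cloud) lies on its positive side.
#'
#' @param cloud A point-cloud tibble with at least 3 points.
#' @param dist_thresh Inlier distance threshold (cm).
#' @param max_iters Number of RANSAC hypotheses.
#' @param seed Optional seed; the fit is deterministic given the seed.
#' @return A `plane_model` list: unit `normal`, `offset` (so that
#'   `normal . p = offset` on the plane) and `inlier_indices`.
#' @export
fit_ground_plane <- function(cloud, dist_thresh = 0.2, max_iters = 1000,
                             seed = NULL) {
  validate_cloud(cloud)
  n <- nrow(cloud)
  if (n < 3) abort("need at least 3 points to fit a plane")
  if (!is.null(seed)) set.seed(seed)
  P <- cloud_matrix(cloud)
  scale_ref <- max(apply(P, 2, function(v) diff(range(v))), 1e-12)

  tri <- matrix(replicate(max_iters, sample.int(n, 3L)), nrow = 3)
  A <- P[tri[1, ], , drop = FALSE]
  e1 <- P[tri[2, ], , drop = FALSE] - A
  e2 <- P[tri[3, ], , drop = FALSE] - A
  N <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- sqrt(rowSums(N^2))
  ok <- nn > 1e-9 * scale_ref^2
  if (!any(ok)) abort("degenerate input: sampled points are collinear")
  best_count <- -1L
  best <- NULL
  chunk <- 200L
  ids <- which(ok)
  for (start in seq(1, length(ids), by = chunk)) {
    sel <- ids[start:min(start + chunk - 1L, length(ids))]
    Nu <- N[sel, , drop = FALSE] / nn[sel]
    offs <- rowSums(Nu * A[sel, , drop = FALSE])
    D <- abs(P %*% t(Nu) - matrix(offs, n, length(sel), byrow = TRUE))
    counts <- colSums(D <= dist_thresh)
    j <- which.max(counts)
    if (counts[j] > best_count) {
      best_count <- counts[j]
      best <- list(normal = Nu[j, ], offset = offs[j])
    }
  }
  if (best_count < 3) abort("degenerate input: no plane supports 3 points")
  # least-squares refinement on inliers
  for (pass in 1:2) {
    d <- abs(P %*% best$normal - best$offset)
    inl <- which(d <= dist_thresh)
    if (length(inl) < 3) break
    ctr <- colMeans(P[inl, , drop = FALSE])
    cv <- crossprod(sweep(P[inl, , drop = FALSE], 2, ctr))
    ev <- eigen(cv, symmetric = TRUE)
    nrm <- ev$vectors[, 3]
    best <- list(normal = nrm / sqrt(sum(nrm^2)), offset = sum(nrm * ctr))
  }
  # orient toward the plant
  ref <- if (has_colors(cloud)) {
    m <- color_filter(cloud)
    if (any(m)) colMeans(P[m, , drop = FALSE]) else colMeans(P)
  } else colMeans(P)
  if (sum(best$normal * ref) - best$offset < 0) {
    best$normal <- -best$normal
    best$offset <- -best$offset
  }
  d <- abs(P %*% best$normal - best$offset)
  structure(list(normal = best$normal, offset = best$offset,
                 inlier_indices = which(d <= dist_thresh),
                 dist_thresh = dist_thresh),
            class = "plane_model")
}

#' Rotation aligning a plane normal with a reference direction
#'
#' Rodrigues rotation about the axis `n1 x n2` by the angle between the two
#' unit vectors, so that `R %*% n1 = n2`. For antiparallel vectors the
#' rotation is by pi about the fixed fallback axis (1, 0, 0) (or (0, 1, 0) if
#' `n1` is parallel to it).
#'
#' @param n1 Unit normal of the fitted ground plane.
#' @param n2 Reference normal (default the +z axis).
#' @return A 3x3 proper rotation matrix.
#' @export
rotation_to_reference <- function(n1, n2 = c(0, 0, 1)) {
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- n2 / sqrt(sum(n2^2))
  ax <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  s <- sqrt(sum(ax^2))
  co <- sum(n1 * n2)
  if (s < 1e-12) {
    if (co > 0) return(diag(3))
    k <- c(1, 0, 0)
    if (abs(sum(k * n1)) > 0.9) k <- c(0, 1, 0)
    k <- k - sum(k * n1) * n1
    k <- k / sqrt(sum(k^2))
    th <- pi
  } else {
    k <- ax / s
    th <- atan2(s, co)
  }
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Green-color filtering
#'
#' Keeps points whose green channel exceeds red by more than `gr_thresh` and
#' blue by more than `gb_thresh` (both strictly); points on the boundary are
#' removed. The default thresholds G-R > 5 and G-B > 30 separate wheat tissue
#' from soil and pot colors.
#'
#' @param cloud A colored point-cloud tibble.
#' @param gr_thresh,gb_thresh Margin thresholds on G-R and G-B.
#' @return A logical keep-mask.
#' @export
color_filter <- function(cloud, gr_thresh = 5, gb_thresh = 30) {
  validate_cloud(cloud, colors = TRUE)
  (cloud$g - cloud$r) > gr_thresh & (cloud$g - cloud$b) > gb_thresh
}

#' @param bins Number of histogram bins.
#' @rdname color_filter
#' @return `color_margin_histogram()`: a tidy tibble with columns `margin`
#'   (`"G-R"` or `"G-B"`), `mid`, and `count`; counts sum to the cloud size
#'   within each margin.
#' @export
color_margin_histogram <- function(cloud, bins = 60) {
  validate_cloud(cloud, colors = TRUE)
  one <- function(v, nm) {
    h <- graphics::hist(v, breaks = bins, plot = FALSE)
    tibble(margin = nm, mid = h$mids, count = h$counts)
  }
  dplyr::bind_rows(one(cloud$g - cloud$r, "G-R"), one(cloud$g - cloud$b, "G-B"))
}

#' Statistical outlier removal
#'
#' For every point, the mean distance to its `k` nearest neighbours is
#' computed; points whose mean distance exceeds `mu + std_ratio * sigma`
#' (mean and standard deviation over all points) are removed.
#'
#' @param cloud A point-cloud tibble with more than `k` points.
#' @param k Neighbour count.
#' @param std_ratio Removal threshold in standard deviations.
#' @return A logical keep-mask.
#' @export
statistical_outlier_removal <- function(cloud, k = 10, std_ratio = 3) {
  validate_cloud(cloud)
  n <- nrow(cloud)
  if (k < 1) abort("k must be >= 1")
  if (n <= k) abort("need more points than k")
  kn <- .cpp_knn(cloud_matrix(cloud), k)
  dbar <- rowMeans(kn$dist)
  dbar <= mean(dbar) + std_ratio * sd(dbar)
}

#' Voxel-grid downsampling
#'
#' One output point per occupied voxel, at the centroid of the voxel's member
#' points (colors averaged and rounded). Output voxels appear in the order of
#' their first member point.
#'
#' @param cloud A point-cloud tibble.
#' @param voxel Voxel edge length (cm).
#' @param mapping Attach the voxel-to-input-row index map (attribute
#'   `voxel_map`)?
#' @return The downsampled cloud.
#' @export
voxel_downsample <- function(cloud, voxel, mapping = FALSE) {
  validate_cloud(cloud)
  if (voxel <= 0) abort("voxel must be > 0")
  n <- nrow(cloud)
  if (!n) return(cloud)
  kx <- floor(cloud$x / voxel); ky <- floor(cloud$y / voxel); kz <- floor(cloud$z / voxel)
  kx <- kx - min(kx); ky <- ky - min(ky); kz <- kz - min(kz)
  M <- max(kx, ky, kz) + 1
  if (M^3 > 2^52) abort("voxel grid too fine for this extent")
  key <- kx + M * (ky + M * kz)
  f <- factor(key, levels = unique(key))
  cols <- intersect(c("x", "y", "z", "r", "g", "b"), names(cloud))
  m <- as.matrix(cloud[cols])
  sums <- rowsum(m, f, reorder = FALSE)
  cnt <- as.vector(rowsum(rep(1, n), f, reorder = FALSE))
  avg <- sums / cnt
  out <- as_tibble(as.data.frame(avg))
  for (cc in intersect(c("r", "g", "b"), cols)) out[[cc]] <- as.integer(round(out[[cc]]))
  if (mapping) attr(out, "voxel_map") <- split(seq_len(n), f)
  out
}

#' Euclidean clustering
#'
#' Connected components of the epsilon-proximity graph: two points share a
#' cluster iff they are linked by a chain of hops no longer than `eps`
#' (grid-hash accelerated, exact distances). Clusters smaller than `min_size`
#' are labelled `-1`.
#'
#' @param cloud A point-cloud tibble.
#' @param eps Hop distance threshold (cm).
#' @param min_size Minimum cluster size.
#' @return An integer label vector (1..K in order of first appearance; -1 for
#'   points in undersized clusters).
#' @export
euclidean_cluster <- function(cloud, eps, min_size = 1) {
  validate_cloud(cloud)
  if (eps <= 0) abort("eps must be > 0")
  .cpp_euclidean_cluster(cloud_matrix(cloud), eps, as.integer(min_size))
}

#' Centroid-cutoff threshold
#'
#' The cut-off height `z_ground + alpha * (z_plant - z_ground)` interpolating
#' between the ground centroid and the plant-color centroid.
#'
#' @param z_ground,z_plant Centroid heights (cm).
#' @param alpha Interpolation factor in `[0, 1]`.
#' @return A `cutoff_params` list with `alpha`, `z_ground`, `z_plant`,
#'   `z_threshold`.
#' @export
cutoff_threshold <- function(z_ground, z_plant, alpha = 0.3) {
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  structure(list(alpha = alpha, z_ground = z_ground, z_plant = z_plant,
                 z_threshold = z_ground + alpha * (z_plant - z_ground)),
            class = "cutoff_params")
}

#' Isolate the plant from a restored scene
#'
#' Implements the centroid-assisted Euclidean clustering segmentation on a
#' scaled, ground-aligned scene: (1) voxel-downsample a working copy; (2) fit
#' the ground with RANSAC and take its centroid, and the centroid of the
#' green (color-filtered) points; (3) form the cut-off threshold
#' (see [cutoff_threshold()]); (4) drop working points below it; (5) cluster
#' the survivors and keep the cluster nearest the plant centroid. The kept
#' cluster is mapped back to full resolution, then color filtering and
#' statistical outlier removal are applied in that order.
#'
#' @param cloud A colored, scale/frame-restored point-cloud tibble.
#' @param alpha Cut-off interpolation factor.
#' @param eps,min_size Euclidean clustering parameters.
#' @param voxel Working-copy voxel size (cm).
#' @param dist_thresh,ransac_iters Ground RANSAC parameters.
#' @param gr_thresh,gb_thresh Color-filter margins.
#' @param sor_k,sor_ratio Statistical-outlier-removal parameters.
#' @param seed Optional seed (RANSAC).
#' @return A list: `cloud` (the clean plant cloud), `indices` (rows of the
#'   input it came from), `cutoff` (the [cutoff_threshold()] parameters) and
#'   `diagnostics` (per-stage point counts).
#' @export
extract_plant <- function(cloud, alpha = 0.3, eps = 1, min_size = 50,
                          voxel = 0.5, dist_thresh = 0.2, ransac_iters = 1000,
                          gr_thresh = 5, gb_thresh = 30,
                          sor_k = 10, sor_ratio = 3, seed = NULL) {
  validate_cloud(cloud, colors = TRUE)
  work <- voxel_downsample(cloud, voxel, mapping = TRUE)
  vm <- attr(work, "voxel_map")
  plane <- fit_ground_plane(work, dist_thresh, ransac_iters, seed)
  z_ground <- mean(work$z[plane$inlier_indices])
  green <- color_filter(work, gr_thresh, gb_thresh)
  if (!any(green)) abort("no plant-colored points")
  plant_ctr <- colMeans(cloud_matrix(work)[green, , drop = FALSE])
  cut <- cutoff_threshold(z_ground, plant_ctr[3], alpha)
  surv <- which(work$z >= cut$z_threshold)
  if (!length(surv)) abort("no points above the cut-off threshold")
  lab <- euclidean_cluster(work[surv, ], eps, min_size)
  if (all(lab == -1)) abort("no cluster of the required size above the cut-off")
  Ps <- cloud_matrix(work[surv, ])
  d2 <- rowSums(sweep(Ps, 2, plant_ctr)^2)
  d2[lab == -1] <- Inf
  keep_lab <- lab[which.min(d2)]
  keep_work <- surv[lab == keep_lab]
  full_idx <- sort(unlist(vm[keep_work], use.names = FALSE))
  sel <- cloud[full_idx, , drop = FALSE]
  m_col <- color_filter(sel, gr_thresh, gb_thresh)
  if (!any(m_col)) abort("no plant-colored points in the selected cluster")
  sel2 <- sel[m_col, , drop = FALSE]
  idx2 <- full_idx[m_col]
  m_sor <- statistical_outlier_removal(sel2, sor_k, sor_ratio)
  list(cloud = sel2[m_sor, , drop = FALSE],
       indices = idx2[m_sor],
       cutoff = cut,
       plane = plane,
       diagnostics = list(n_input = nrow(cloud), n_work = nrow(work),
                          n_above_cutoff = length(surv),
                          n_cluster_full = length(full_idx),
                          n_after_color = nrow(sel2),
                          n_after_sor = sum(m_sor),
                          n_clusters = max(lab)))
}

#' Restore real-world scale and upright frame
#'
#' Measures the marker (unless `virtual_width` is supplied), rescales the
#' cloud by `S = real_width / W_virtual`, fits the ground plane by RANSAC on
#' a voxel-downsampled working copy, rotates the cloud so the ground normal
#' maps to +z, and translates it so the ground inliers average z = 0.
#'
#' @inheritParams measure_marker_width
#' @param real_width Physical marker width (cm).
#' @param virtual_width Optional manual marker width measurement (cloud
#'   units); skips the automated measurement.
#' @param voxel Working-copy voxel size for the plane search (cm).
#' @param dist_thresh,ransac_iters Ground RANSAC parameters.
#' @return A list: `cloud` (restored), `transform`
#'   ([similarity_transform()]), `plane` (on the scaled cloud), and `scale`
#'   (the [estimate_scale()] result).
#' @export
restore_scale_and_frame <- function(cloud, real_width = 3, virtual_width = NULL,
                                    white_thresh = 200, voxel = 0.5,
                                    dist_thresh = 0.2, ransac_iters = 1000,
                                    seed = NULL) {
  validate_cloud(cloud)
  w <- virtual_width %||%
    measure_marker_width(cloud, white_thresh = white_thresh, seed = seed)
  est <- estimate_scale(w, real_width)
  scaled <- apply_scale(cloud, est$s)
  work <- voxel_downsample(scaled, voxel)
  plane <- fit_ground_plane(work, dist_thresh, ransac_iters, seed)
  R <- rotation_to_reference(plane$normal)
  rotated <- apply_rotation(scaled, R)
  d <- abs(cloud_matrix(scaled) %*% plane$normal - plane$offset)
  ground_idx <- which(d <= dist_thresh)
  z0 <- mean(rotated$z[ground_idx])
  rotated$z <- rotated$z - z0
  list(cloud = rotated,
       transform = similarity_transform(est$s, R, z_offset = -z0),
       plane = plane, scale = est,
       diagnostics = list(n_ground = length(ground_idx)))
}
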