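#' Plant height
#'
#' Height is the z-range of the plant cloud, `H = z_max - z_min`, after the
#' scene has been levelled (ground at z = 0). Using the range rather than the
#' maximum alone cancels any residual vertical offset.
#'
#' @param cloud A non-empty point-cloud tibble.
#' @return Height (cm).
#' @export
plant_height <- function(cloud) {
  validate_cloud(cloud)
  if (!nrow(cloud)) abort("empty point cloud")
  max(cloud$z) - min(cloud$z)
}

#' Crown area
#'
#' The canopy is projected to the ground plane. In `"diameter"` mode `L_max`
#' is the diameter of the projected convex hull (the maximum horizontal
#' distance) and `W_max` the extent of the projections on the perpendicular
#' direction, so the result is rotation invariant; `C = L_max * W_max`. In
#' `"aabb"` mode the axis-aligned bounding rectangle of the projection is
#' used instead (these differ: a 4 x 1 rectangle rotated by 45 degrees has an
#' axis-aligned base of about 3.54 x 3.54 but a diameter rectangle of
#' 4.12 x 0.97).
#'
#' @param cloud A point-cloud tibble with at least 2 points.
#' @param mode `"diameter"` (default) or `"aabb"`.
#' @return A one-row tibble: `crown_area` (cm^2), `l_max`, `w_max` (cm),
#'   `mode`.
#' @export
crown_area <- function(cloud, mode = c("diameter", "aabb")) {
  mode <- match.arg(mode)
  validate_cloud(cloud)
  if (nrow(cloud) < 2) abort("need at least 2 points")
  xy <- cbind(cloud$x, cloud$y)
  if (mode == "aabb") {
    ex <- diff(range(xy[, 1]))
    ey <- diff(range(xy[, 2]))
    l <- max(ex, ey); w <- min(ex, ey)
    return(tibble(crown_area = l * w, l_max = l, w_max = w, mode = mode))
  }
  uxy <- unique(xy)
  hull <- if (nrow(uxy) >= 3) uxy[grDevices::chull(uxy), , drop = FALSE] else uxy
  if (nrow(hull) < 2) {
    return(tibble(crown_area = 0, l_max = 0, w_max = 0, mode = mode))
  }
  # diameter over hull vertex pairs
  h <- nrow(hull)
  best <- c(0, 1, 1)
  for (i in seq_len(h - 1)) {
    d2 <- (hull[(i + 1):h, 1] - hull[i, 1])^2 + (hull[(i + 1):h, 2] - hull[i, 2])^2
    j <- which.max(d2)
    if (d2[j] > best[1]) best <- c(d2[j], i, i + j)
  }
  l <- sqrt(best[1])
  if (l == 0) return(tibble(crown_area = 0, l_max = 0, w_max = 0, mode = mode))
  dir <- (hull[best[3], ] - hull[best[2], ]) / l
  perp <- c(-dir[2], dir[1])
  proj <- xy %*% perp
  w <- diff(range(proj))
  tibble(crown_area = l * w, l_max = l, w_max = w, mode = mode)
}

#' Convex hull of a plant cloud
#'
#' Quickhull over the 3D points; the volume is the space enclosed by the
#' outermost convex polyhedron, a standard proxy for the space the plant
#' occupies.
#'
#' @param cloud A point-cloud tibble with at least 4 non-coplanar points.
#' @return `convex_hull()`: a list with `mesh` (a [triangle_mesh()] of the
#'   hull facets), `volume` (cm^3) and `area` (cm^2). `convex_volume()`: the
#'   volume only.
#' @export
convex_hull <- function(cloud) {
  validate_cloud(cloud)
  if (nrow(cloud) < 4) abort("need at least 4 points for a 3D hull")
  res <- .cpp_quickhull(cloud_matrix(cloud))
  list(mesh = triangle_mesh(cloud_matrix(cloud), res$faces),
       volume = res$volume, area = res$area)
}

#' @rdname convex_hull
#' @export
convex_volume <- function(cloud) {
  convex_hull(cloud)$volume
}

#' Plant surface area by ball-pivoting reconstruction
#'
#' The cloud is voxel-downsampled for uniformity, per-point normals are
#' estimated and consistently oriented by propagation along a minimum
#' spanning tree of the k-NN graph, a triangle mesh is reconstructed by ball
#' pivoting, and the surface area is the sum of all facet areas. With
#' `radii = NULL` the ball radii are 1.5, 3 and 6 times the mean
#' nearest-neighbour spacing of the downsampled cloud.
#'
#' @param cloud A point-cloud tibble (>= 100 points after downsampling).
#' @param voxel Downsampling voxel size (cm).
#' @param radii Ball radii (cm), or `NULL` for automatic.
#' @param k_normals Neighbourhood size for normal estimation.
#' @return A list: `area` (cm^2) and `mesh` (a [triangle_mesh()]).
#' @export
surface_area <- function(cloud, voxel = 0.2, radii = NULL, k_normals = 15) {
  validate_cloud(cloud)
  down <- voxel_downsample(cloud, voxel)
  if (nrow(down) < 100) abort("need at least 100 points after voxel downsampling")
  P <- cloud_matrix(down)
  N <- oriented_normals(P, k = k_normals)
  spacing <- mean(.cpp_knn(P, 1)$dist)
  radii <- radii %||% (c(1.5, 3, 6) * spacing)
  F <- .cpp_ball_pivot(P, N, radii)
  if (!nrow(F)) abort("ball pivoting produced no faces; try larger radii")
  mesh <- triangle_mesh(P, F)
  list(area = mesh_area(mesh), mesh = mesh)
}

#' Align a leaf cloud with its principal axis
#'
#' PCA on the leaf coordinates; the cloud is rotated so the principal axis
#' maps to +x (right-handed frame). The two x-extreme ends are compared by
#' their mean height in the original frame: the lower end is the leaf base
#' (wheat leaves attach below their tips) and is placed at smaller x.
#'
#' @param leaf A point-cloud tibble with at least 30 points.
#' @param end_frac Fraction of the x-extent treated as the end zones when
#'   deciding base vs tip.
#' @return A list: `cloud` (aligned tibble, extra columns preserved), `base`
#'   and `tip` (row indices), `rotation` (applied matrix), `center`.
#' @export
leaf_align <- function(leaf, end_frac = 0.05) {
  validate_cloud(leaf)
  if (nrow(leaf) < 30) abort("need at least 30 leaf points")
  P <- cloud_matrix(leaf)
  ctr <- colMeans(P)
  pc <- prcomp(P, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] == 0 || (pc$sdev[1] / pc$sdev[2])^2 < 2) {
    abort("no dominant axis: eigenvalue ratio below 2")
  }
  V <- pc$rotation
  if (det(V) < 0) V[, 3] <- -V[, 3]
  A <- sweep(P, 2, ctr) %*% V
  rx <- range(A[, 1])
  lo_end <- A[, 1] <= rx[1] + end_frac * diff(rx)
  hi_end <- A[, 1] >= rx[2] - end_frac * diff(rx)
  # base = the end lower in the original frame
  if (mean(P[lo_end, 3]) > mean(P[hi_end, 3])) {
    A[, 1] <- -A[, 1]
    A[, 2] <- -A[, 2]
    V[, 1] <- -V[, 1]
    V[, 2] <- -V[, 2]
  }
  out <- set_coords(leaf, A)
  list(cloud = out, base = which.min(A[, 1]), tip = which.max(A[, 1]),
       rotation = t(V), center = ctr)
}

#' Fit the leaf midrib by local polynomial regression
#'
#' On a PCA-aligned leaf, `y(x)` and `z(x)` are fitted by local weighted
#' polynomial regression (degree-`degree` fits with tricube weights over the
#' `span` fraction of points; `stats::loess`) and evaluated at `stations`
#' equally spaced x-positions. If a station's window is too thin the span is
#' widened once before failing.
#'
#' @param aligned An aligned leaf cloud (the `cloud` element of
#'   [leaf_align()], or such a tibble).
#' @param stations Number of evaluation stations M (>= 10).
#' @param span Local regression span (fraction of points).
#' @param degree Local polynomial degree.
#' @return The midrib polyline: a tibble with columns `x`, `y`, `z`
#'   (x-monotone).
#' @export
fit_midrib <- function(aligned, stations = 30, span = 0.3, degree = 2) {
  if (is.list(aligned) && !is.data.frame(aligned) && !is.null(aligned$cloud)) {
    aligned <- aligned$cloud
  }
  validate_cloud(aligned)
  if (stations < 10) abort("need at least 10 stations (M >= 10)")
  n <- nrow(aligned)
  if (n * span < degree + 2) span <- min(1, 2 * span)
  if (n * span < degree + 2) abort("too few points in the regression span")
  xs <- seq(min(aligned$x), max(aligned$x), length.out = stations)
  fit1 <- function(v) {
    fit <- tryCatch(
      loess(v ~ x, data = data.frame(x = aligned$x, v = v), span = span,
            degree = degree, family = "gaussian",
            control = stats::loess.control(surface = "direct")),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        loess(v ~ x, data = data.frame(x = aligned$x, v = v),
              span = min(1, 2 * span), degree = degree, family = "gaussian",
              control = stats::loess.control(surface = "direct")),
        error = function(e) abort("local polynomial fit failed even after widening the span"))
    }
    predict(fit, newdata = data.frame(x = xs))
  }
  tibble(x = xs, y = fit1(aligned$y), z = fit1(aligned$z))
}

#' Leaf length: arc length of the fitted midrib
#'
#' @param midrib A midrib polyline tibble (>= 2 points).
#' @return Arc length (cm); always at least the base-to-tip chord.
#' @export
leaf_length <- function(midrib) {
  validate_cloud(midrib)
  if (nrow(midrib) < 2) abort("midrib polyline needs at least 2 points")
  P <- cloud_matrix(midrib)
  sum(sqrt(rowSums(diff(P)^2)))
}

#' Maximum leaf width perpendicular to the midrib
#'
#' At every midrib station, the points within a slab of one station spacing
#' are projected on the plane perpendicular to the local midrib tangent; the
#' width at that station is their extent along the dominant in-plane
#' direction (the leaf surface direction). The leaf width is the maximum over
#' stations.
#'
#' @param aligned Aligned leaf cloud (see [leaf_align()]).
#' @param midrib Fitted midrib polyline ([fit_midrib()]).
#' @param min_slab Minimum number of points a station needs to be measured.
#' @return Width (cm).
#' @export
leaf_width <- function(aligned, midrib, min_slab = 5) {
  if (is.list(aligned) && !is.data.frame(aligned) && !is.null(aligned$cloud)) {
    aligned <- aligned$cloud
  }
  validate_cloud(aligned)
  validate_cloud(midrib)
  M <- nrow(midrib)
  P <- cloud_matrix(aligned)
  mid <- cloud_matrix(midrib)
  spacing <- (max(midrib$x) - min(midrib$x)) / (M - 1)
  tang <- rbind(mid[2, ] - mid[1, ],
                (mid[3:M, ] - mid[1:(M - 2), ]) / 2,
                mid[M, ] - mid[M - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  widths <- rep(NA_real_, M)
  for (j in seq_len(M)) {
    in_slab <- abs(P[, 1] - mid[j, 1]) <= spacing / 2
    if (sum(in_slab) < min_slab) next
    t_j <- tang[j, ]
    # orthonormal basis of the plane perpendicular to the tangent
    a <- if (abs(t_j[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * t_j) * t_j
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(t_j[2] * e1[3] - t_j[3] * e1[2],
            t_j[3] * e1[1] - t_j[1] * e1[3],
            t_j[1] * e1[2] - t_j[2] * e1[1])
    D <- sweep(P[in_slab, , drop = FALSE], 2, mid[j, ])
    uv <- cbind(D %*% e1, D %*% e2)
    ev <- eigen(crossprod(sweep(uv, 2, colMeans(uv))), symmetric = TRUE)
    wdir <- ev$vectors[, 1]
    proj <- uv %*% wdir
    widths[j] <- diff(range(proj))
  }
  if (all(is.na(widths))) abort("no station had enough slab points to measure width")
  max(widths, na.rm = TRUE)
}

#' Full phenotype extraction for one plant
#'
#' Plant-level traits (height, crown area, convex-hull volume, ball-pivoting
#' surface area) are computed on the full plant cloud; leaf-level traits
#' (midrib length, maximum width) are computed per leaf region of the
#' segmentation after voxel-downsampling each leaf. Per-trait failures are
#' recorded and do not stop the remaining traits.
#'
#' @param cloud The preprocessed plant cloud.
#' @param segmentation Optional [region_growing()] result; without it only
#'   plant-level traits are returned.
#' @param crown_mode Passed to [crown_area()].
#' @param surface_voxel,leaf_voxel Voxel sizes for surface reconstruction and
#'   leaf trait extraction (cm).
#' @param stations,span,degree Midrib fitting parameters ([fit_midrib()]).
#' @param bp_radii Optional ball-pivoting radii ([surface_area()]).
#' @return A `plant_phenotypes` list: `plant` (one-row tibble), `leaves`
#'   (one row per measured leaf region) and `failures` (character messages).
#' @export
phenotype_plant <- function(cloud, segmentation = NULL,
                            crown_mode = "diameter", surface_voxel = 0.2,
                            leaf_voxel = 0.2, stations = 30, span = 0.3,
                            degree = 2, bp_radii = NULL) {
  validate_cloud(cloud)
  failures <- character()
  grab <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      failures <<- c(failures, paste0(what, ": ", conditionMessage(e)))
      NA_real_
    })
  }
  h <- grab("plant_height", plant_height(cloud))
  cr <- tryCatch(crown_area(cloud, crown_mode), error = function(e) {
    failures <<- c(failures, paste0("crown_area: ", conditionMessage(e)))
    tibble(crown_area = NA_real_, l_max = NA_real_, w_max = NA_real_,
           mode = crown_mode)
  })
  vol <- grab("convex_volume", convex_volume(cloud))
  sa <- grab("surface_area",
             surface_area(cloud, voxel = surface_voxel, radii = bp_radii)$area)
  plant <- tibble(n_points = nrow(cloud), plant_height = h,
                  l_max = cr$l_max, w_max = cr$w_max, crown_area = cr$crown_area,
                  convex_volume = vol, surface_area = sa)
  leaves <- tibble(leaf_region = integer(), n_points = integer(),
                   leaf_length = double(), leaf_width = double())
  if (!is.null(segmentation)) {
    split <- split_stem_leaves(segmentation, cloud)
    for (id in split$leaf_regions) {
      sub <- cloud[segmentation$labels == id, , drop = FALSE]
      row <- tryCatch({
        down <- voxel_downsample(sub, leaf_voxel)
        al <- leaf_align(down)
        mid <- fit_midrib(al$cloud, stations = stations, span = span,
                          degree = degree)
        tibble(leaf_region = id, n_points = nrow(sub),
               leaf_length = leaf_length(mid),
               leaf_width = leaf_width(al$cloud, mid))
      }, error = function(e) {
        failures <<- c(failures, paste0("leaf region ", id, ": ",
                                        conditionMessage(e)))
        tibble(leaf_region = id, n_points = nrow(sub),
               leaf_length = NA_real_, leaf_width = NA_real_)
      })
      leaves <- dplyr::bind_rows(leaves, row)
    }
  }
  structure(list(plant = plant, leaves = leaves, failures = failures),
            class = "plant_phenotypes")
}

#' @export
print.plant_phenotypes <- function(x, ...) {
  cat("<plant_phenotypes>\n")
  print(x$plant)
  if (nrow(x$leaves)) {
    cat("leaves:\n")
    print(x$leaves)
  }
  if (length(x$failures)) cat("failures:", length(x$failures), "\n")
  invisible(x)
}

#' @export
tidy.plant_phenotypes <- function(x, ...) {
  x$plant
}
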