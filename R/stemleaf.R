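#' Per-point normals and curvature
#'
#' PCA of each point's k-nearest-neighbour neighbourhood: the normal is the
#' eigenvector of the smallest eigenvalue (sign-disambiguated toward the +z
#' hemisphere, then +x, then +y), and the curvature is the surface variation
#' `lambda0 / (lambda0 + lambda1 + lambda2)`, which is 0 on a plane and at
#' most 1/3.
#'
#' @param cloud A point-cloud tibble with more than `k` points.
#' @param k Neighbourhood size (>= 3).
#' @return A `local_geometry` list: `normals` (n x 3 unit rows), `curvature`
#'   (length n), and `k`.
#' @export
estimate_local_geometry <- function(cloud, k = 30) {
  validate_cloud(cloud)
  if (k < 3) abort("k must be >= 3")
  if (nrow(cloud) <= k) abort("need more points than k")
  gg <- .cpp_local_geometry(cloud_matrix(cloud), as.integer(k))
  structure(list(normals = gg$normals, curvature = as.numeric(gg$curvature),
                 k = as.integer(k)),
            class = "local_geometry")
}

#' Region-growing segmentation on normals and curvature
#'
#' Regions start from the unvisited point of smallest curvature. A neighbour
#' joins the current region when the (unsigned) angle between its normal and
#' the normal of the point it was reached from is at most `angle_thresh`; it
#' additionally becomes part of the growth front (a new seed) only when its
#' curvature is at most `curv_thresh`. The process repeats until every point
#' has been visited; regions smaller than `min_region` are labelled `-1`
#' (unclassified). Ties are broken by lowest point index, so the labelling is
#' deterministic.
#'
#' @param cloud A point-cloud tibble.
#' @param geom A [estimate_local_geometry()] result computed with the same
#'   neighbourhood convention (if `NULL`, computed here with `k`).
#' @param angle_thresh Normal angle threshold (degrees).
#' @param curv_thresh Curvature threshold for growth-front promotion.
#' @param k Neighbourhood size for the growing graph.
#' @param min_region Minimum region size.
#' @return A `segmentation_result` list: `labels` (1..K, -1 unclassified) and
#'   `region_count`.
#' @export
region_growing <- function(cloud, geom = NULL, angle_thresh = 8,
                           curv_thresh = 0.05, k = 30, min_region = 100) {
  validate_cloud(cloud)
  geom <- geom %||% estimate_local_geometry(cloud, k)
  stopifnot(inherits(geom, "local_geometry"))
  n <- nrow(cloud)
  if (n <= k) abort("need more points than k")
  kn <- .cpp_knn(cloud_matrix(cloud), as.integer(k))
  nb <- kn$idx
  N <- geom$normals
  curv <- geom$curvature
  cos_thr <- cos(angle_thresh * pi / 180)
  ord <- order(curv, seq_len(n))  # curvature, ties by index
  visited <- logical(n)
  labels <- rep(-1L, n)
  region <- 0L
  ptr <- 1L
  queue <- integer(n)
  while (ptr <= n) {
    while (ptr <= n && visited[ord[ptr]]) ptr <- ptr + 1L
    if (ptr > n) break
    seed <- ord[ptr]
    region <- region + 1L
    visited[seed] <- TRUE
    labels[seed] <- region
    queue[1L] <- seed
    qlen <- 1L
    while (qlen > 0L) {
      p <- queue[qlen]
      qlen <- qlen - 1L
      cand <- nb[p, ]
      cand <- cand[!visited[cand]]
      if (!length(cand)) next
      ang_ok <- abs(N[cand, , drop = FALSE] %*% N[p, ]) >= cos_thr
      adm <- cand[ang_ok]
      if (!length(adm)) next
      visited[adm] <- TRUE
      labels[adm] <- region
      front <- adm[curv[adm] <= curv_thresh]
      nf <- length(front)
      if (nf) {
        if (qlen + nf > length(queue)) queue <- c(queue, integer(n))
        queue[qlen + seq_len(nf)] <- front
        qlen <- qlen + nf
      }
    }
  }
  sizes <- tabulate(labels[labels > 0], nbins = region)
  keep <- which(sizes >= min_region)
  remap <- rep(-1L, region)
  remap[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0] <- remap[labels[labels > 0]]
  structure(list(labels = out, region_count = length(keep)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result> ", x$region_count, " regions, ",
      sum(x$labels == -1L), " unclassified of ", length(x$labels), " points\n",
      sep = "")
  invisible(x)
}

#' Classify grown regions into stems and leaves
#'
#' A region is a stem candidate when its shape is strongly linear
#' (`(lambda1 - lambda2) / lambda1 >= linearity_min` on the region's 3D
#' covariance eigenvalues) and its principal axis is within 30 degrees of
#' vertical (elevation >= `elevation_min` degrees); every other region is a
#' leaf.
#'
#' @param seg A [region_growing()] result.
#' @param cloud The segmented point-cloud tibble.
#' @param linearity_min Minimum PCA linearity for a stem.
#' @param elevation_min Minimum elevation of the principal axis (degrees).
#' @return A list with `stem_regions`, `leaf_regions` (integer region ids)
#'   and `features` (per-region tibble).
#' @export
split_stem_leaves <- function(seg, cloud, linearity_min = 0.95,
                              elevation_min = 60) {
  stopifnot(inherits(seg, "segmentation_result"))
  validate_cloud(cloud)
  ids <- setdiff(sort(unique(seg$labels)), -1L)
  if (!length(ids)) {
    return(list(stem_regions = integer(), leaf_regions = integer(),
                features = tibble(region = integer(), n = integer(),
                                  linearity = double(), elevation = double(),
                                  class = character())))
  }
  P <- cloud_matrix(cloud)
  rows <- lapply(ids, function(id) {
    Q <- P[seg$labels == id, , drop = FALSE]
    ev <- eigen(crossprod(sweep(Q, 2, colMeans(Q))), symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    lin <- if (lam[1] > 0) (lam[1] - lam[2]) / lam[1] else 0
    axis <- ev$vectors[, 1]
    elev <- asin(min(1, abs(axis[3]))) * 180 / pi
    tibble(region = id, n = nrow(Q), linearity = lin, elevation = elev,
           class = if (lin >= linearity_min && elev >= elevation_min)
             "stem" else "leaf")
  })
  feats <- dplyr::bind_rows(rows)
  list(stem_regions = feats$region[feats$class == "stem"],
       leaf_regions = feats$region[feats$class == "leaf"],
       features = feats)
}

# consistently oriented normals: sign propagation along a minimum spanning
# tree of the k-NN graph (edge weight 1 - |ni . nj|), rooted at the topmost
# point whose normal is forced upward
oriented_normals <- function(P, k = 15) {
  n <- nrow(P)
  geom <- .cpp_local_geometry(P, as.integer(min(k, n - 1)))
  N <- geom$normals
  kn <- .cpp_knn(P, as.integer(min(k, n - 1)))
  from <- rep(seq_len(n), ncol(kn$idx))
  to <- as.vector(kn$idx)
  w <- 1 - abs(rowSums(N[from, , drop = FALSE] * N[to, , drop = FALSE])) + 1e-9
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  g <- igraph::simplify(g, edge.attr.comb = "min")
  mt <- igraph::mst(g)
  el <- igraph::as_edgelist(mt, names = FALSE)
  storage.mode(el) <- "integer"
  adj <- vector("list", n)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  visited <- logical(n)
  ord <- order(P[, 3], decreasing = TRUE)
  for (root in ord) {
    if (visited[root]) next
    if (N[root, 3] < 0) N[root, ] <- -N[root, ]
    visited[root] <- TRUE
    stack <- root
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (q in adj[[p]]) {
        if (visited[q]) next
        if (sum(N[q, ] * N[p, ]) < 0) N[q, ] <- -N[q, ]
        visited[q] <- TRUE
        stack <- c(stack, q)
      }
    }
  }
  N
}
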