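test_that("local geometry: planes are flat, cylinders are radial", {
  set.seed(1)
  flat <- make_ribbon(2000, length = 10, width = 10)
  geom <- estimate_local_geometry(flat, k = 20)
  expect_lte(max(geom$curvature), 1e-3)
  ang <- acos(pmin(1, abs(geom$normals[, 3]))) * 180 / pi
  expect_lt(max(ang), 1)

  cyl <- make_cylinder(8000, radius = 1, height = 10)
  gcy <- estimate_local_geometry(cyl, k = 15)
  radial <- cbind(cyl$x, cyl$y, 0)
  radial <- radial / sqrt(rowSums(radial^2))
  dots <- abs(rowSums(gcy$normals * radial))
  expect_lt(quantile(acos(pmin(1, dots)) * 180 / pi, 0.99), 5)
})

test_that("curvature is bounded by 1/3 on arbitrary clouds", {
  set.seed(2)
  rc <- as_cloud(matrix(rnorm(900), ncol = 3))
  geom <- estimate_local_geometry(rc, k = 8)
  expect_true(all(geom$curvature >= 0))
  expect_true(all(geom$curvature <= 1 / 3 + 1e-12))
  expect_error(estimate_local_geometry(rc[1:5, ], k = 8), "more points")
})

test_that("two orthogonal patches grow into exactly two regions", {
  set.seed(3)
  a <- make_ribbon(1500, length = 5, width = 5)                  # z = 0 plane
  b <- make_ribbon(1500, length = 5, width = 5, dir = c(0, 0, 1),
                   up = c(1, 0, 0))                              # x-z plane
  cl <- dplyr::bind_rows(a, b)
  seg <- region_growing(cl, k = 15, angle_thresh = 10, curv_thresh = 0.1,
                        min_region = 100)
  expect_equal(seg$region_count, 2)
  # one flat patch stays a single region
  seg1 <- region_growing(a, k = 15, angle_thresh = 10, min_region = 100)
  expect_equal(seg1$region_count, 1)
  expect_true(all(seg1$labels == 1))
})

test_that("region growing is deterministic", {
  set.seed(4)
  cl <- make_ribbon(800, length = 8, width = 2, jitter = 0.01)
  a <- region_growing(cl, k = 12, min_region = 10)
  b <- region_growing(cl, k = 12, min_region = 10)
  expect_identical(a$labels, b$labels)
})

test_that("regions are connected components of the growing graph", {
  sc <- quiet_scene(seed = 3)
  plant <- sc$cloud[sc$truth$label == "plant", ]
  seg <- region_growing(plant, k = 18, angle_thresh = 12, curv_thresh = 0.1,
                        min_region = 10)
  kn <- wheatpheno:::.cpp_knn(cloud_coords(plant), 18L)
  n <- nrow(plant)
  edges <- cbind(rep(seq_len(n), ncol(kn$idx)), as.vector(kn$idx))
  edges <- rbind(edges, edges[, 2:1])  # symmetrise
  adj <- split(edges[, 2], edges[, 1])
  for (id in setdiff(unique(seg$labels), -1L)) {
    members <- which(seg$labels == id)
    inreg <- rep(FALSE, n); inreg[members] <- TRUE
    seen <- rep(FALSE, n)
    front <- members[1]; seen[front] <- TRUE
    while (length(front)) {
      nb <- unique(unlist(adj[as.character(front)], use.names = FALSE))
      nxt <- nb[inreg[nb] & !seen[nb]]
      seen[nxt] <- TRUE
      front <- nxt
    }
    expect_true(all(seen[members]))
  }
})

test_that("stems look linear and vertical, ribbons look like leaves", {
  set.seed(5)
  cyl <- make_cylinder(1200, radius = 0.3, height = 12)
  ribbon <- make_ribbon(800, length = 10, width = 2)
  cl <- dplyr::bind_rows(cyl, dplyr::mutate(ribbon, x = x + 10))
  seg <- structure(list(labels = rep(c(1L, 2L), c(nrow(cyl), nrow(ribbon))),
                        region_count = 2L), class = "segmentation_result")
  sp <- split_stem_leaves(seg, cl)
  expect_equal(sp$stem_regions, 1L)
  expect_equal(sp$leaf_regions, 2L)

  empty <- structure(list(labels = integer(), region_count = 0L),
                     class = "segmentation_result")
  sp0 <- split_stem_leaves(empty, cl[0, ])
  expect_equal(length(sp0$stem_regions), 0)
  expect_equal(length(sp0$leaf_regions), 0)
})

test_that("seedling leaves are recovered with high per-leaf accuracy", {
  for (sd_i in c(3, 21)) {
    sc <- quiet_scene(seed = sd_i)
    plant <- sc$cloud[sc$truth$label == "plant", ]
    truth_leaf <- sc$truth$leaf_id[sc$truth$label == "plant"]
    geom <- estimate_local_geometry(plant, k = 6)
    seg <- region_growing(plant, geom, k = 24, angle_thresh = 10,
                          curv_thresh = 0.1, min_region = 10)
    regs <- setdiff(unique(seg$labels), -1L)
    maj <- vapply(regs, function(r) {
      tt <- table(truth_leaf[seg$labels == r])
      as.integer(names(which.max(tt)))
    }, 1L)
    for (lid in sort(unique(truth_leaf[truth_leaf > 0]))) {
      members <- truth_leaf == lid
      matched <- seg$labels %in% regs[maj == lid]
      expect_gte(sum(matched & members) / sum(members), 0.95)
      expect_gte(sum(matched & members) / sum(matched), 0.95)
    }
  }
})

test_that("unclassified fraction shrinks as the angle threshold loosens", {
  sc <- quiet_scene(seed = 9)
  plant <- sc$cloud[sc$truth$label == "plant", ]
  geom <- estimate_local_geometry(plant, k = 6)
  fr <- vapply(c(6, 12, 20), function(ang) {
    seg <- region_growing(plant, geom, k = 24, angle_thresh = ang,
                          curv_thresh = 0.1, min_region = 10)
    mean(seg$labels == -1L)
  }, 0)
  expect_true(all(diff(fr) <= 0))
})
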