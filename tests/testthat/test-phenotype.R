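test_that("plant height is the z-range", {
  cl <- as_cloud(cbind(0, 0, c(2.0, 30, 47.3)))
  expect_equal(plant_height(cl), 45.3)
  expect_equal(plant_height(cl[1, ]), 0)
  expect_error(plant_height(cl[0, ]), "empty")
})

test_that("noiseless synthetic plants recover their designed height", {
  sc <- quiet_scene(seed = 16)
  plant <- sc$cloud[sc$truth$label == "plant", ]
  expect_equal(plant_height(plant), sc$truth$plant_height, tolerance = 0.05)
})

test_that("crown rectangle matches brute force over pair directions", {
  sq <- as_cloud(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0))
  cr <- crown_area(sq)
  expect_equal(cr$l_max, sqrt(2), tolerance = 1e-12)
  expect_equal(cr$w_max, sqrt(2), tolerance = 1e-12)
  expect_equal(cr$crown_area, 2, tolerance = 1e-12)

  set.seed(1)
  for (i in 1:5) {
    xy <- matrix(runif(80), ncol = 2)
    cl <- tibble::tibble(x = xy[, 1], y = xy[, 2], z = runif(40))
    got <- crown_area(cl)
    ref <- bf_crown(xy)
    expect_equal(got$l_max, unname(ref["L"]), tolerance = 1e-12)
    expect_equal(got$crown_area, unname(ref["C"]), tolerance = 1e-12)
  }
})

test_that("crown handles discs, degenerate inputs and aabb mode", {
  set.seed(2)
  a <- runif(4000, 0, 2 * pi); r <- 5 * sqrt(runif(4000))
  disc <- tibble::tibble(x = r * cos(a), y = r * sin(a), z = 0)
  expect_equal(crown_area(disc)$crown_area, 100, tolerance = 0.02 * 100)

  line <- as_cloud(cbind(seq(0, 7, length.out = 10), 0, 0))
  cr <- crown_area(line)
  expect_equal(cr$l_max, 7)
  expect_equal(cr$crown_area, 0)

  box <- as_cloud(cbind(c(0, 4, 4, 0), c(0, 0, 1, 1), 0))
  aabb <- crown_area(box, mode = "aabb")
  expect_equal(aabb$l_max, 4)
  expect_equal(aabb$w_max, 1)
  expect_error(crown_area(box[1, ]), "2 points")
})

test_that("crown diameter mode is rotation invariant", {
  set.seed(3)
  cl <- as_cloud(matrix(runif(120), ncol = 3))
  base <- crown_area(cl)$crown_area
  th <- runif(1, 0, 2 * pi)
  rot <- cl
  rot$x <- cl$x * cos(th) - cl$y * sin(th)
  rot$y <- cl$x * sin(th) + cl$y * cos(th)
  expect_equal(crown_area(rot)$crown_area, base, tolerance = 1e-9)
})

test_that("convex hull volume matches closed forms and the oracle", {
  cube <- as_cloud(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  expect_equal(convex_volume(cube), 1, tolerance = 1e-12)
  tet <- as_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(convex_volume(tet), 1 / 6, tolerance = 1e-12)

  set.seed(4)
  P <- matrix(rnorm(3 * 200), ncol = 3)
  P <- P / sqrt(rowSums(P^2)) * runif(200)^(1 / 3)
  expect_equal(convex_volume(as_cloud(P)), bf_hull_volume(P), tolerance = 1e-9)

  flat <- as_cloud(cbind(runif(10), runif(10), 0))
  expect_error(convex_volume(flat), "coplanar")
  expect_error(convex_volume(as_cloud(cbind(1:5, 2 * (1:5), 3 * (1:5)))),
               "collinear")
})

test_that("hull volume is bounded by the bounding box", {
  set.seed(5)
  cl <- as_cloud(matrix(rnorm(600), ncol = 3))
  bbox <- prod(apply(cloud_coords(cl), 2, function(v) diff(range(v))))
  expect_lte(convex_volume(cl), bbox)
})

test_that("ball-pivoting surface area matches flat and spherical geometry", {
  set.seed(6)
  patch <- make_ribbon(6000, length = 10, width = 10)
  sa <- surface_area(patch, voxel = 0.15)
  expect_equal(sa$area, 100, tolerance = 0.05 * 100)
  expect_gt(nrow(sa$mesh$faces), 0)
  expect_gt(sa$area, 0)

  sph <- make_sphere(4000, radius = 5)
  sa2 <- surface_area(sph, voxel = 0.2)
  expect_equal(sa2$area, 4 * pi * 25, tolerance = 0.10 * 4 * pi * 25)
})

test_that("leaf alignment maps the principal axis to x and finds the base", {
  set.seed(7)
  ribbon <- make_ribbon(600, length = 10, width = 1, dir = c(1, 1, 1))
  al <- leaf_align(ribbon)
  expect_equal(diff(range(al$cloud$x)), 10, tolerance = 0.05)
  # base end is the lower end in the original frame
  expect_lt(ribbon$z[al$base], ribbon$z[al$tip])
  expect_lt(al$cloud$x[al$base], al$cloud$x[al$tip])

  iso <- as_cloud(matrix(rnorm(300), ncol = 3))
  expect_error(leaf_align(iso), "dominant axis")
  expect_error(leaf_align(ribbon[1:10, ]), "30")
})

test_that("base/tip are correct on generated leaves", {
  set.seed(8)
  for (i in 1:10) {
    spec <- leaf_spec(length = runif(1, 8, 25), max_width = runif(1, 0.8, 1.8),
                      azimuth = runif(1, 0, 360), droop = runif(1, 0.2, 0.8))
    gl <- generate_leaf(spec, seed = i)
    al <- leaf_align(gl$cloud)
    base_xyz <- cloud_coords(gl$cloud)[al$base, ]
    tip_xyz <- cloud_coords(gl$cloud)[al$tip, ]
    truth <- cloud_coords(gl$midrib)
    # the detected base sits nearer the midrib origin than the detected tip
    expect_lt(sum((base_xyz - truth[1, ])^2), sum((base_xyz - truth[200, ])^2))
    expect_lt(sum((tip_xyz - truth[200, ])^2), sum((tip_xyz - truth[1, ])^2))
  }
})

test_that("midrib fitting follows the centerline of straight and bent leaves", {
  set.seed(9)
  flat <- make_ribbon(2000, length = 10, width = 1, jitter = 0.005)
  al <- leaf_align(flat)
  mid <- fit_midrib(al$cloud)
  expect_lte(max(abs(mid$y)), 0.05)
  expect_lte(max(abs(mid$z)), 0.05)
  expect_true(all(diff(mid$x) > 0))
  expect_error(fit_midrib(al$cloud, stations = 2), "M >= 10")

  gl <- generate_leaf(leaf_spec(length = 20, max_width = 1.5, azimuth = 0,
                                droop = 0.6), seed = 10)
  al2 <- leaf_align(gl$cloud)
  mid2 <- fit_midrib(al2$cloud)
  # compare the fitted curve with the generator midrib mapped into the same
  # frame; error is measured transverse to x, against the bend amplitude
  truth <- sweep(cloud_coords(gl$midrib), 2, al2$center) %*% t(al2$rotation)
  yt <- approx(truth[, 1], truth[, 2], xout = mid2$x, rule = 2)$y
  zt <- approx(truth[, 1], truth[, 3], xout = mid2$x, rule = 2)$y
  rms <- sqrt(mean((mid2$y - yt)^2 + (mid2$z - zt)^2))
  amplitude <- max(diff(range(truth[, 2])), diff(range(truth[, 3])))
  expect_lt(rms, 0.02 * amplitude)
})

test_that("leaf length integrates the midrib polyline", {
  straight <- tibble::tibble(x = seq(0, 10, length.out = 50), y = 0, z = 0)
  expect_equal(leaf_length(straight), 10, tolerance = 1e-12)

  th <- seq(0, pi, length.out = 200)
  semi <- tibble::tibble(x = 5 * cos(th), y = 5 * sin(th), z = 0)
  expect_equal(leaf_length(semi), pi * 5, tolerance = 0.001 * pi * 5)

  set.seed(10)
  gl <- generate_leaf(leaf_spec(length = 15, max_width = 1.2, droop = 0.5),
                      seed = 11)
  al <- leaf_align(gl$cloud)
  mid <- fit_midrib(al$cloud)
  chord <- sqrt(sum((mid[nrow(mid), ] - mid[1, ])^2))
  expect_gte(leaf_length(mid), chord)
})

test_that("leaf width recovers flat and tapered designs", {
  set.seed(11)
  flat <- make_ribbon(2000, length = 10, width = 1)
  al <- leaf_align(flat)
  mid <- fit_midrib(al$cloud)
  expect_equal(leaf_width(al$cloud, mid), 1, tolerance = 0.05)

  gl <- generate_leaf(leaf_spec(length = 18, max_width = 1.4, droop = 0.5),
                      seed = 12, noise_sd = 0.02)
  al2 <- leaf_align(gl$cloud)
  mid2 <- fit_midrib(al2$cloud)
  w <- leaf_width(al2$cloud, mid2)
  expect_equal(w, 1.4, tolerance = 0.05 * 1.4)
  # width never exceeds the hull diameter
  xy <- cloud_coords(gl$cloud)
  expect_lte(w, max(dist(xy)))
})

test_that("phenotype traits scale with the expected powers", {
  set.seed(12)
  sc <- quiet_scene(seed = 18)
  plant <- sc$cloud[sc$truth$label == "plant", ]
  s <- 1.7
  big <- apply_scale(plant, s)
  expect_equal(plant_height(big), s * plant_height(plant), tolerance = 1e-9)
  expect_equal(crown_area(big)$l_max, s * crown_area(plant)$l_max,
               tolerance = 1e-9)
  expect_equal(crown_area(big)$crown_area, s^2 * crown_area(plant)$crown_area,
               tolerance = 1e-9)
  expect_equal(convex_volume(big), s^3 * convex_volume(plant),
               tolerance = 1e-6)
  expect_equal(surface_area(big, voxel = 0.2 * s)$area,
               s^2 * surface_area(plant, voxel = 0.2)$area,
               tolerance = 0.02 * s^2 * surface_area(plant, voxel = 0.2)$area)
})

test_that("traits are invariant to rotation about the z axis", {
  sc <- quiet_scene(seed = 19)
  plant <- sc$cloud[sc$truth$label == "plant", ]
  th <- 0.83
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  rot <- apply_rotation(plant, Rz)
  expect_equal(plant_height(rot), plant_height(plant), tolerance = 1e-9)
  expect_equal(convex_volume(rot), convex_volume(plant), tolerance = 1e-6)
  expect_equal(crown_area(rot)$crown_area, crown_area(plant)$crown_area,
               tolerance = 1e-9)
})

test_that("phenotype_plant runs end to end on a seedling scene", {
  sc <- quiet_scene(seed = 20)
  ext <- extract_plant(sc$cloud, seed = 20)
  geom <- estimate_local_geometry(ext$cloud, k = 6)
  seg <- region_growing(ext$cloud, geom, k = 24, angle_thresh = 10,
                        curv_thresh = 0.1, min_region = 50)
  phen <- phenotype_plant(ext$cloud, seg)
  expect_true(all(is.finite(unlist(phen$plant[-1]))))
  expect_equal(phen$plant$plant_height, sc$truth$plant_height,
               tolerance = 0.5)
  expect_gt(nrow(phen$leaves), 0)

  # without a segmentation only plant traits are produced
  p2 <- phenotype_plant(ext$cloud)
  expect_equal(nrow(p2$leaves), 0)
  expect_true(is.finite(p2$plant$plant_height))

  # determinism
  p3 <- phenotype_plant(ext$cloud, seg)
  expect_identical(phen$plant, p3$plant)
  expect_identical(phen$leaves, p3$leaves)
})
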