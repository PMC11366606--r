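test_that("a straight (droop 0) leaf spans its designed length", {
  spec <- leaf_spec(length = 10, max_width = 1, droop = 0)
  gl <- generate_leaf(spec, density = 150, seed = 1)
  P <- cloud_coords(gl$cloud)
  pc <- prcomp(P)
  expect_equal(diff(range(pc$x[, 1])), 10, tolerance = 0.02)
  # true midrib polyline integrates to the designed arc length
  seg <- sqrt(rowSums(diff(cloud_coords(gl$midrib))^2))
  expect_equal(sum(seg), 10, tolerance = 1e-3)
})

test_that("midrib arc length is exact for curved leaves too", {
  for (dr in c(0.3, 0.7, 1)) {
    gl <- generate_leaf(leaf_spec(length = 20, max_width = 1.5, droop = dr),
                        seed = 2)
    seg <- sqrt(rowSums(diff(cloud_coords(gl$midrib))^2))
    expect_equal(sum(seg), 20, tolerance = 20 * 0.001)
  }
})

test_that("leaf generation is deterministic per seed and validates density", {
  spec <- leaf_spec(length = 8, max_width = 1, droop = 0.4)
  a <- generate_leaf(spec, seed = 11)
  b <- generate_leaf(spec, seed = 11)
  expect_identical(a$cloud, b$cloud)
  expect_error(generate_leaf(spec, density = 1), "fewer than 50")
})

test_that("leaf specs enforce their invariants", {
  expect_error(leaf_spec(length = -1, max_width = 0.5), "length")
  expect_error(leaf_spec(length = 5, max_width = 6), "max_width")
  expect_error(leaf_spec(length = 5, max_width = 1, droop = 2), "droop")
  expect_error(plant_spec(2, c(10), list(list(), list())), "tiller height")
})

test_that("noiseless scene z-range equals the designed plant height exactly", {
  sc <- quiet_scene(seed = 4)
  pz <- sc$cloud$z[sc$truth$label == "plant"]
  expect_equal(max(pz) - min(pz), sc$truth$plant_height, tolerance = 1e-12)
})

test_that("scene labels partition the cloud", {
  sc <- quiet_scene(seed = 6)
  expect_equal(length(sc$truth$label), nrow(sc$cloud))
  expect_false(any(is.na(sc$truth$label)))
  expect_setequal(unique(sc$truth$label),
                  c("plant", "pot", "soil", "ground", "marker"))
  # leaf memberships only on plant points
  expect_true(all(is.na(sc$truth$leaf_id[sc$truth$label != "plant"])))
})

test_that("marker extent scales linearly with true_scale", {
  spec <- stage_preset("seedling", "moderate", seed = 8, true_scale = 0.5,
                       tilt_deg = 0, noise_sd = 0, outlier_frac = 0)
  sc <- generate_scene(spec)
  m <- sc$cloud[sc$truth$label == "marker", ]
  pc <- prcomp(cloud_coords(m))
  expect_equal(diff(range(pc$x[, 2])), 1.5, tolerance = 0.02)
})

test_that("undoing scale and tilt reproduces the canonical frame", {
  spec <- stage_preset("tillering", "moderate", seed = 9, true_scale = 0.7,
                       tilt_deg = 12, noise_sd = 0, outlier_frac = 0)
  sc <- generate_scene(spec)
  raw <- cloud_coords(sc$cloud)
  undone <- (raw %*% sc$truth$tilt) / sc$truth$true_scale
  expect_lt(max(abs(undone - sc$truth$canonical)), 1e-9)
})

test_that("plant colors always clear the filtering margins; scenery never does", {
  spec <- stage_preset("jointing", "moderate", seed = 10, true_scale = 1,
                       tilt_deg = 0, noise_sd = 0.05, outlier_frac = 0)
  sc <- generate_scene(spec)
  keep <- color_filter(sc$cloud)
  is_plant <- sc$truth$label == "plant"
  expect_gte(mean(keep[is_plant]), 0.99)
  expect_equal(sum(keep[!is_plant]), 0)
})

test_that("stage presets are ordered and respond to cultivar profiles", {
  heights <- vapply(names(wheatpheno:::stage_table), function(st) {
    sc <- quiet_scene(stage = st, seed = 14)
    sc$truth$plant_height
  }, 0)
  expect_true(all(diff(heights) >= 0))

  seedling <- stage_preset("seedling", "moderate", seed = 14)
  expect_equal(seedling$plant$tillers, 1)
  expect_lte(sum(lengths(seedling$plant$leaves)), 5)

  loose <- stage_preset("booting", "loose_many_tillers", seed = 14)
  compact <- stage_preset("booting", "compact_few_tillers", seed = 14)
  expect_gt(loose$plant$tillers, compact$plant$tillers)
})

test_that("scene generation is deterministic per seed", {
  a <- generate_scene(stage_preset("seedling", "moderate", seed = 5))
  b <- generate_scene(stage_preset("seedling", "moderate", seed = 5))
  expect_identical(a$cloud, b$cloud)
  expect_identical(a$truth$plant_height, b$truth$plant_height)
})
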