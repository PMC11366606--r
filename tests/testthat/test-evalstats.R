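test_that("accuracy metrics follow their defining formulas exactly", {
  y <- c(1, 2, 3); yh <- c(1, 2, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, yh), 0.5)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, yh), sqrt(1 / 3))
  expect_equal(rmse(y, y + 2.5), 2.5)
  expect_equal(rrmse(rep(50, 4), rep(50, 4) + c(1, -1, 1, -1)), 2)
  expect_equal(rrmse(y, y), 0)
  expect_equal(rrmse(10 * y, 10 * yh), rrmse(y, yh))
  expect_error(r_squared(c(1, 1), c(1, 2)), "constant")
  expect_error(rrmse(c(-1, 1), c(0, 0)), "zero")
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("metrics match brute-force formula evaluation on random vectors", {
  set.seed(1)
  for (i in 1:20) {
    y <- rnorm(50); yh <- y + rnorm(50, 0, 0.3)
    expect_equal(r_squared(y, yh),
                 1 - sum((y - yh)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    expect_equal(rmse(y, yh), sqrt(sum((y - yh)^2) / 50), tolerance = 1e-12)
    expect_equal(rrmse(y + 10, yh + 10),
                 100 * sqrt(sum((y - yh)^2) / 50) / mean(y + 10),
                 tolerance = 1e-12)
  }
})

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  an <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  # SSB = 6, SSW = 6, df (2, 6) -> F = (6/2)/(6/6) = 3
  expect_equal(an$F, 3, tolerance = 1e-12)
  expect_equal(an$df_between, 2)
  expect_equal(an$df_within, 6)
  expect_equal(an$p, stats::pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-10)

  same <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3)))
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_equal(same$stars, "ns")
})

test_that("ANOVA F is invariant to shifts and scalings", {
  set.seed(2)
  g <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  f0 <- one_way_anova(g)$F
  expect_equal(one_way_anova(lapply(g, `+`, 100))$F, f0, tolerance = 1e-9)
  expect_equal(one_way_anova(lapply(g, `*`, 3.7))$F, f0, tolerance = 1e-9)
})

test_that("degenerate zero-variance groups are flagged with p = 0", {
  an <- one_way_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_true(an$degenerate)
  expect_equal(an$p, 0)
  expect_equal(glance(an)$stars, "**")
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("significance stars follow the p <= 0.05 / p <= 0.01 convention", {
  expect_equal(wheatpheno:::p_stars(0.05), "*")
  expect_equal(wheatpheno:::p_stars(0.01), "**")
  expect_equal(wheatpheno:::p_stars(0.049), "*")
  expect_equal(wheatpheno:::p_stars(0.2), "ns")
})

test_that("trait validation joins, scores and reports orphans", {
  truth <- tibble::tibble(plant_id = 1:5, h = c(10, 20, 30, 40, 50))
  exact <- tibble::tibble(plant_id = 1:5, h = c(10, 20, 30, 40, 50))
  v <- validate_traits(truth, exact, by = "plant_id")
  expect_equal(v$metrics$r_squared, 1)
  expect_equal(v$metrics$rmse, 0)
  expect_equal(v$metrics$rrmse, 0)

  part <- tibble::tibble(plant_id = c(1:3, 8, 9), h = c(10.5, 19, 31, 1, 2))
  v2 <- validate_traits(truth, part, by = "plant_id")
  expect_equal(v2$metrics$n, 3)
  expect_equal(nrow(v2$orphans$truth), 2)
  expect_equal(nrow(v2$orphans$extracted), 2)
  expect_error(validate_traits(truth, dplyr::mutate(part, plant_id = 100:104),
                               by = "plant_id"),
               "zero matched")
})

test_that("injected measurement error is recovered as RMSE", {
  set.seed(3)
  n <- 2000
  truth <- tibble::tibble(plant_id = 1:n, h = runif(n, 10, 60))
  noisy <- dplyr::mutate(truth, h = h + rnorm(n, 0, 0.8))
  v <- validate_traits(truth, noisy, by = "plant_id")
  expect_equal(v$metrics$rmse, 0.8, tolerance = 0.1 * 0.8)
})

test_that("growth dynamics summarises stages and flags injected differences", {
  set.seed(4)
  stages <- c("seedling", "tillering")
  dd <- expand.grid(stage = stages, cultivar = c("A", "B"), rep = 1:6,
                    stringsAsFactors = FALSE)
  dd$crown_area <- ifelse(dd$cultivar == "A", 100, 300) + rnorm(nrow(dd), 0, 5)
  dd$plant_height <- 20 + rnorm(nrow(dd), 0, 1)
  dyn <- growth_dynamics(dd, traits = c("crown_area", "plant_height"),
                         stage_order = c(stages, "jointing"))
  expect_equal(dyn$gaps, "jointing")
  cr <- dyn$anova[dyn$anova$trait == "crown_area", ]
  expect_true(all(cr$stars == "**"))

  # single cultivar: means only, no ANOVA
  solo <- growth_dynamics(dd[dd$cultivar == "A", ], traits = "crown_area")
  expect_equal(nrow(solo$anova), 0)
  expect_equal(nrow(solo$summary), length(stages))

  const <- dd
  const$crown_area <- 7
  dc <- growth_dynamics(const[const$cultivar == "A", ], traits = "crown_area")
  expect_true(all(dc$summary$mean == 7))
})

test_that("tidy and glance methods return tibbles", {
  an <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4)))
  expect_s3_class(tidy(an), "tbl_df")
  expect_s3_class(glance(an), "tbl_df")
  truth <- tibble::tibble(plant_id = 1:3, h = 1:3 * 1.0)
  v <- validate_traits(truth, truth, by = "plant_id")
  expect_s3_class(tidy(v), "tbl_df")
  expect_s3_class(glance(v), "tbl_df")
})
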