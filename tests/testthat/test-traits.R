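test_that("stem height from Fiedler-ordered bins recovers a straight stem", {
  pc <- tube_cloud(len = 70, radius = 1.5, density = 6)
  g <- build_similarity_graph(pc, 18)
  f <- compute_fiedler(g, pc)$fiedler
  h <- main_stem_height(pc$coords, f)
  expect_lt(abs(h - 70) / 70, 0.02)

  # rigid rotation leaves the estimate unchanged
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3) %*%
       matrix(c(1, 0, 0, 0, cos(0.5), -sin(0.5), 0, sin(0.5), cos(0.5)), 3, 3)
  h2 <- main_stem_height(pc$coords %*% R, f)
  expect_equal(h2, h, tolerance = 1e-6)

  # degenerate input falls back to the up-axis extent
  few <- pc$coords[1:3, ]
  expect_equal(main_stem_height(few, f[1:3]), diff(range(few[, 3])))
  expect_error(main_stem_height(pc$coords[0, ], numeric(0)), "no main-stem")
})

test_that("Bezier blade areas: flat limit, quadratic scaling, curvature", {
  set.seed(1)
  sq <- cbind(runif(2000), runif(2000), 0)
  a1 <- blade_area(sq)
  expect_lt(abs(a1 - 1), 0.02)
  expect_equal(blade_area(sq * 10) / a1, 100, tolerance = 1e-6)

  # elliptical blade from the generator against pi*a*b
  bl <- plantseg3d:::.sample_blade(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), 9, 5.4, 8)
  expect_lt(abs(blade_area(bl) - pi * 9 * 5.4) / (pi * 9 * 5.4), 0.05)

  # a half-cylinder is developable with area pi*r*l; a tensor patch of high
  # enough degree recovers it, a bicubic smooths the rim and undershoots
  u <- runif(6000, 0, 30); thh <- runif(6000, 0, pi)
  hc <- cbind(u, 5 * cos(thh), 5 * sin(thh))
  true_a <- pi * 5 * 30
  expect_lt(abs(blade_area(hc, degree = 6, grid = 40) - true_a) / true_a, 0.05)
  expect_gt(blade_area(hc) / true_a, 0.85)

  # too few points falls back to the hull area with a warning
  expect_warning(a_small <- blade_area(sq[1:10, ]), "convex-hull")
  expect_true(a_small > 0)
})

test_that("leaf area index is the blade-to-base area ratio", {
  coords <- rbind(c(0, 0, 0), c(10, 10, 7))
  expect_equal(leaf_area_index(50, coords)$lai, 0.5)
  expect_equal(leaf_area_index(numeric(0), coords)$lai, 0)
  expect_equal(leaf_area_index(c(25, 25), coords)$lai, 0.5)   # additivity
  expect_equal(leaf_area_index(c(50, 50), coords)$lai, 1)     # doubling doubles
  flat <- rbind(c(0, 0, 0), c(0, 10, 5))
  expect_error(leaf_area_index(10, flat), "degenerate")

  # translation leaves LAI unchanged (the base is axis-aligned by design,
  # so only quarter-turns about the up axis are exactly neutral)
  set.seed(2)
  cloud <- matrix(runif(300, -5, 5), ncol = 3)
  l1 <- leaf_area_index(30, cloud)$lai
  expect_equal(leaf_area_index(30, cloud + 100)$lai, l1, tolerance = 1e-9)
  quarter <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(leaf_area_index(30, cloud %*% quarter)$lai, l1, tolerance = 1e-9)
})

test_that("trait extraction runs on a full segmentation", {
  out <- generate_plant(small_plant_spec())
  seg <- suppressWarnings(run_pipeline(out$cloud, pipeline_config(seed = 0)))
  tr <- extract_traits(seg)
  expect_gt(tr$stem_height, 0)
  expect_true(all(tr$blade_areas >= 0))
  expect_equal(tr$lai, tr$total_blade_area / tr$bbox_base_area)
})
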