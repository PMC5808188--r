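test_that("scene_spec enforces its invariants", {
  expect_error(scene_spec(depth_range = c(5, 2)), "depth_range")
  expect_error(scene_spec(class_means = matrix(0.5, 4, 3) ,
                          class_sd = rep(2, 4)), "\\[0, 1\\]")
  bad <- default_class_means(); bad[2, ] <- bad[1, ]
  expect_error(scene_spec(class_means = bad), "pairwise distinct")
  expect_error(scene_spec(pixel_size = 0), "pixel_size")
  expect_error(scene_spec(class_prior = rep(0, 4)), "class_prior")
})

test_that("depth surface respects range, trend and determinism", {
  expect_error(generate_depth_surface(scene_spec(rows = 3, cols = 3)),
               "degenerate grid")
  # zero-width range -> constant raster
  z5 <- generate_depth_surface(scene_spec(rows = 20, cols = 20,
                                          depth_range = c(5, 5)))
  expect_true(all(z5$values == 5))
  spec <- scene_spec(rows = 60, cols = 60, rng_seed = 42)
  z <- generate_depth_surface(spec)
  expect_gte(min(z$values), 0.8)
  expect_lte(max(z$values), 18.9)
  # shore-to-deep trend: column means increase left to right
  cm <- colMeans(z$values)
  expect_gt(cor(cm, seq_along(cm)), 0.99)
  expect_identical(generate_depth_surface(spec)$values, z$values)
})

test_that("habitat maps are complete, depth-structured and deterministic", {
  spec <- scene_spec(rows = 60, cols = 60, rng_seed = 42)
  z <- generate_depth_surface(spec)
  h <- generate_habitat_map(spec, z)
  expect_setequal(unique(as.vector(h$values)), 1:4)
  expect_identical(generate_habitat_map(spec, z)$values, h$values)
  # every class can supply the requested points
  need <- spec$n_train + spec$n_val
  expect_true(all(tabulate(h$values, 4) >= need))
  # single-class prior -> uniform map
  spec1 <- scene_spec(rows = 60, cols = 60, class_prior = c(0, 0, 0, 1))
  h1 <- generate_habitat_map(spec1, z)
  expect_true(all(h1$values == 4L))
  # a tiny grid cannot supply 100 points per class
  specs <- scene_spec(rows = 6, cols = 6, rng_seed = 1)
  zs <- generate_depth_surface(specs)
  expect_error(generate_habitat_map(specs, zs), "cannot supply")
})

test_that("scene generation is bit-reproducible and points are disjoint", {
  spec <- scene_spec(rows = 80, cols = 80, rng_seed = 13)
  a <- simulate_scene(spec)
  b <- simulate_scene(spec)
  expect_identical(a$surface$values, b$surface$values)
  expect_identical(a$train_points, b$train_points)
  expect_identical(a$depth_points, b$depth_points)
  # per-class counts match the spec exactly
  expect_equal(unname(table(a$train_points$class)), rep(50L, 4),
               ignore_attr = TRUE)
  expect_equal(unname(table(a$val_points$class)), rep(50L, 4),
               ignore_attr = TRUE)
  # no coordinate appears in both sets
  key <- function(p) paste(p$x, p$y)
  expect_length(intersect(key(a$train_points), key(a$val_points)), 0)
})

test_that("geographic split places train and validation in opposite halves", {
  spec <- scene_spec(rows = 80, cols = 80, rng_seed = 13,
                     geographic_split = TRUE)
  sc <- simulate_scene(spec)
  mid <- 40 * spec$grid$pixel_size
  expect_true(all(sc$train_points$x < mid))
  expect_true(all(sc$val_points$x > mid))
})

test_that("the noise-free forward render inverts exactly (round trip)", {
  sc <- clean_scene()
  rb <- correct_water_column(sc$surface, sc$truth_depth,
                             sc$spec$optics)
  expect_lte(max(abs(rb$values - sc$truth_bottom$values)), 1e-10)
  # and with Z = 0 everywhere, surface equals the class-mean bottom exactly
  spec0 <- scene_spec(rows = 40, cols = 40, depth_range = c(0, 0),
                      class_sd = rep(0, 4), sensor_noise_sd = 0,
                      n_points_per_class_train = 5, n_points_per_class_val = 5,
                      rng_seed = 2)
  z0 <- generate_depth_surface(spec0)
  h0 <- generate_habitat_map(spec0, z0)
  sc0 <- render_surface_reflectance(h0, z0, spec0)
  mus <- spec0$class_means
  for (k in 1:4) {
    pix <- which(h0$values == k)
    for (b in 1:3)
      expect_true(all(sc0$surface$values[, , b][pix] == mus[k, b]))
  }
})

test_that("attenuation pulls the sand signal toward the asymptote with depth", {
  # oracle: |R - R_inf| must fall across depth deciles for a bright bottom
  sc <- cached("decile_scene",
               simulate_scene(scene_spec(rows = 200, cols = 200, rng_seed = 42)))
  opt <- sc$spec$optics
  sand <- sc$truth_habitat$values == 4L
  z <- sc$truth_depth$values[sand]
  dev475 <- abs(sc$surface$values[, , 1][sand] - opt$R_inf[1])
  dec <- cut(z, breaks = quantile(z, probs = seq(0, 1, 0.1)),
             include.lowest = TRUE)
  med <- tapply(dev475, dec, mean)
  expect_true(all(diff(med) < 0))
})

test_that("a written scene directory is complete and self-describing", {
  d <- withr::local_tempdir()
  sc <- clean_scene()
  write_scene_dir(sc, d)
  expect_true(all(file.exists(file.path(d, c(
    "surface.json", "surface_b475.asc", "surface_b555.asc", "surface_b658.asc",
    "truth_depth.asc", "truth_habitat.asc", "truth_habitat.asc.classes.json",
    "train_points.csv", "val_points.csv", "depth_points.csv", "manifest.json")))))
  man <- read_config(file.path(d, "manifest.json"))
  expect_equal(man$rng_seed, sc$spec$rng_seed)
  expect_equal(man$sensor_noise_sd, sc$spec$sensor_noise_sd)
  back <- read_scene(file.path(d, "surface"))
  expect_identical(back$values, sc$surface$values)
})
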