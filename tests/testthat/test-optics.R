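optx <- optical_constants()

test_that("optical constants are validated", {
  expect_equal(optx$Kd, c(0.067, 0.078, 0.134))
  expect_equal(optx$R_inf, c(0.033, 0.024, 0.017))
  expect_equal(optx$t, 0.54)
  expect_equal(optx$Q, pi)
  expect_error(optical_constants(Kd = c(0, 0.078, 0.134)), "Kd")
  expect_error(optical_constants(R_inf = c(1, 0.02, 0.02)), "R_inf")
  expect_error(optical_constants(t = 1.2), "t must")
  expect_error(optical_constants(Kd = c(0.1, 0.1)), "equal length")
})

test_that("surface_to_rrs applies Rrs = t*R/Q and is linear", {
  expect_equal(surface_to_rrs(flat_scene(0), optx)$values,
               flat_scene(0)$values)
  s <- flat_scene(pi)
  expect_equal(surface_to_rrs(s, optx)$values[1, 1, 1], 0.54)
  s2 <- flat_scene(0.033)
  expect_equal(surface_to_rrs(s2, optx)$values[1, 1, 1], 0.54 * 0.033 / pi)
  # linearity: Rrs(a*R) = a*Rrs(R)
  set.seed(2)
  v <- array(runif(300), dim = c(10, 10, 3))
  a <- 0.37
  r1 <- surface_to_rrs(reflectance_scene(v), optx)$values
  r2 <- surface_to_rrs(reflectance_scene(a * v), optx)$values
  expect_equal(r2, a * r1)
  expect_error(surface_to_rrs(flat_scene(0.1, stage = "bottom_Rb"), optx),
               "stage")
})

test_that("estimate_deep_reflectance averages unmasked pixels in the polygon", {
  s <- flat_scene(0.042, rows = 20, cols = 20)
  ring <- read_polygon("POLYGON ((0 0, 50 0, 50 50, 0 50, 0 0))")
  est <- estimate_deep_reflectance(s, ring)
  expect_equal(unname(est$R_inf), rep(0.042, 3))
  expect_equal(est$n_pixels, 100)  # 10x10 pixels at 5 m inside 50x50 m
  # 4-pixel polygon with band values {0.02, 0.02, 0.04, 0.04} -> 0.03
  v <- array(0.1, dim = c(20, 20, 3))
  v[19, 1, ] <- 0.02; v[20, 1, ] <- 0.02; v[19, 2, ] <- 0.04; v[20, 2, ] <- 0.04
  s2 <- reflectance_scene(v, grid = s$grid)
  est2 <- estimate_deep_reflectance(s2, read_polygon("POLYGON ((0 0, 10 0, 10 10, 0 10, 0 0))"))
  expect_equal(unname(est2$R_inf), rep(0.03, 3))
  expect_equal(est2$n_pixels, 4)
  expect_error(estimate_deep_reflectance(
    s, read_polygon("POLYGON ((500 500, 501 500, 501 501, 500 501, 500 500))")),
    "no unmasked pixels")
})

test_that("deep-water region of a noise-free scene recovers configured R_inf", {
  # render a bottom equal to R_inf: the model fixed point at any depth
  rows <- 20; cols <- 20
  rb <- array(rep(optx$R_inf, each = rows * cols), dim = c(rows, cols, 3))
  bottom <- reflectance_scene(rb, grid = scene_grid(rows, cols), stage = "bottom_Rb")
  z <- depth_raster(matrix(seq(1, 25, length.out = rows * cols), rows, cols))
  surf <- forward_shallow_reflectance(bottom, z, optx)
  ring <- read_polygon("POLYGON ((0 0, 100 0, 100 100, 0 100, 0 0))")
  est <- estimate_deep_reflectance(surf, ring)
  expect_equal(unname(est$R_inf), optx$R_inf, tolerance = 1e-12)
})

test_that("forward model matches hand evaluation and its fixed points", {
  z0 <- depth_raster(matrix(0, 5, 5))
  b <- flat_scene(0.2, rows = 5, cols = 5, stage = "bottom_Rb")
  expect_equal(forward_shallow_reflectance(b, z0, optx)$values, b$values)
  # Rb = R_inf is invariant at any depth
  rb <- array(rep(optx$R_inf, each = 25), dim = c(5, 5, 3))
  binf <- reflectance_scene(rb, stage = "bottom_Rb")
  z <- depth_raster(matrix(runif(25, 0, 20), 5, 5))
  expect_equal(forward_shallow_reflectance(binf, z, optx)$values, rb)
  # hand value: Rb=0.20, R_inf=0.033, Kd=0.067, Z=10
  z10 <- depth_raster(matrix(10, 5, 5))
  out <- forward_shallow_reflectance(b, z10, optx)
  expect_equal(out$values[1, 1, 1], 0.033 + 0.167 * exp(-1.34))
  expect_error(forward_shallow_reflectance(b, depth_raster(matrix(0, 4, 4)), optx),
               "grid mismatch")
})

test_that("water-column inversion is the exact inverse of the forward model", {
  set.seed(7)
  n <- 50
  rb <- array(runif(n * n * 3, 0, 0.3), dim = c(n, n, 3))
  bottom <- reflectance_scene(rb, stage = "bottom_Rb")
  z <- depth_raster(matrix(runif(n * n, 0, 18.9), n, n))
  surf <- forward_shallow_reflectance(bottom, z, optx)
  back <- correct_water_column(surf, z, optx)
  expect_lte(max(abs(back$values - rb)), 1e-10)
  expect_identical(back$stage, "bottom_Rb")
  # Z = 0 and R = R_inf trivial cases
  surf0 <- flat_scene(0.1)
  expect_equal(correct_water_column(surf0, depth_raster(matrix(0, 10, 10)), optx)$values,
               surf0$values)
  rinf_s <- reflectance_scene(array(rep(optx$R_inf, each = 25), dim = c(5, 5, 3)))
  zany <- depth_raster(matrix(13, 5, 5))
  expect_equal(correct_water_column(rinf_s, zany, optx)$values, rinf_s$values)
})

test_that("forward reflectance is monotone in depth toward the asymptote", {
  zs <- seq(0, 30, by = 0.5)
  for (k in 1:3) {
    bright <- optx$R_inf[k] + (0.25 - optx$R_inf[k]) * exp(-2 * optx$Kd[k] * zs)
    dark <- optx$R_inf[k] + (0.005 - optx$R_inf[k]) * exp(-2 * optx$Kd[k] * zs)
    expect_true(all(diff(bright) < 0))       # Rb > R_inf: decreasing
    expect_true(all(diff(dark) > 0))         # Rb < R_inf: increasing
    expect_true(all(bright > optx$R_inf[k]))
    expect_true(all(dark < optx$R_inf[k]))
  }
  # same behaviour through the scene API
  b <- flat_scene(0.25, rows = 1, cols = 61, stage = "bottom_Rb")
  z <- depth_raster(matrix(zs, 1, 61), scene_grid(1, 61))
  r <- forward_shallow_reflectance(b, z, optx)$values[1, , 1]
  expect_true(all(diff(r) < 0))
})

test_that("out-of-range inversions are counted, then clamped or masked", {
  # deep pixel with surface value above the asymptote blows up on inversion
  v <- array(0.2, dim = c(3, 3, 3))
  s <- reflectance_scene(v)
  z <- depth_raster(matrix(20, 3, 3))
  out <- correct_water_column(s, z, optx, out_of_range = "clamp")
  expect_gt(attr(out, "n_out_of_range"), 0)
  expect_true(all(out$values >= 0 & out$values <= 1))
  out2 <- correct_water_column(s, z, optx, out_of_range = "mask")
  expect_true(all(out2$mask))
})

test_that("deep mask thresholds at the optically deep limit and keeps values", {
  sc <- clean_scene()
  z <- sc$truth_depth
  shallow <- apply_deep_mask(sc$surface, z, limit_m = 50)
  expect_identical(shallow$mask, sc$surface$mask)   # nothing deeper than 50 m
  alldeep <- apply_deep_mask(sc$surface, z, limit_m = 0.1)
  expect_true(all(alldeep$mask))
  lim <- 16.5
  m <- apply_deep_mask(sc$surface, z, limit_m = lim)
  expect_equal(sum(!m$mask), sum(z$values <= lim))  # direct-threshold oracle
  expect_identical(m$values, sc$surface$values)
  expect_error(apply_deep_mask(sc$surface, z, limit_m = -1), "limit_m")
})

test_that("every optics operation conserves the input mask", {
  sc <- clean_scene()
  s <- sc$surface
  s$mask[3, 4] <- TRUE
  expect_true(surface_to_rrs(s, optx)$mask[3, 4])
  expect_true(correct_water_column(s, sc$truth_depth, optx)$mask[3, 4])
  b <- sc$truth_bottom; b$mask[5, 6] <- TRUE
  expect_true(forward_shallow_reflectance(b, sc$truth_depth, optx)$mask[5, 6])
  expect_true(apply_deep_mask(s, sc$truth_depth, 16.5)$mask[3, 4])
})
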