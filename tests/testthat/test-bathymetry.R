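# Printed site-specific polynomial used as a generating oracle throughout.
site_poly <- c(24.135, -70.038, 51.571)

test_that("log_ratio is ln(num/den) with the expected symmetries", {
  v <- array(0.05, dim = c(8, 8, 3))
  s <- reflectance_scene(v, stage = "Rrs")
  expect_equal(unique(as.vector(log_ratio(s))), 0)     # equal bands
  v2 <- v; v2[, , 1] <- exp(1) * v2[, , 2]
  s2 <- reflectance_scene(v2, stage = "Rrs")
  expect_equal(unique(as.vector(log_ratio(s2))), 1)    # ratio e -> 1
  x_fwd <- log_ratio(s2, 475, 555)
  x_rev <- log_ratio(s2, 555, 475)
  expect_equal(as.vector(x_rev), as.vector(-x_fwd))    # antisymmetry
  # nonpositive Rrs: masked and counted, not fatal
  v3 <- v; v3[1, 1, 1] <- 0
  s3 <- reflectance_scene(v3, stage = "Rrs")
  x3 <- log_ratio(s3)
  expect_true(is.na(x3[1, 1]))
  expect_equal(attr(x3, "n_invalid"), 1)
  expect_error(log_ratio(flat_scene(0.1)), "stage")
})

test_that("fitting noise-free samples of the site polynomial recovers it", {
  set.seed(42)
  x <- runif(32, 0.6, 1.4)
  z <- eval_poly_oracle(site_poly, x)
  m <- fit_depth_polynomial(x, z)
  expect_equal(m$coefficients, site_poly, tolerance = 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(m$n_points, 32)
  # 3 non-collinear points: exact interpolation, zero residuals
  m3 <- fit_depth_polynomial(c(0, 1, 2), c(5, 2, 7))
  expect_equal(m3$r_squared, 1, tolerance = 1e-12)
  expect_equal(m3$residual_sd, 0)
  expect_error(fit_depth_polynomial(rep(1, 10), runif(10)), "rank-deficient")
})

test_that("residual SD converges to the generating noise SD", {
  set.seed(9)
  n <- 1e4
  sigma <- 1.3
  x <- runif(n, 0.5, 1.5)
  z <- eval_poly_oracle(site_poly, x) + rnorm(n, sd = sigma)
  m <- fit_depth_polynomial(x, z)
  expect_equal(m$residual_sd, sigma, tolerance = 0.05)
})

test_that("fit r-squared equals an independently computed 1 - SSres/SStot", {
  set.seed(10)
  x <- runif(40, 0, 2)
  z <- eval_poly_oracle(site_poly, x) + rnorm(40, sd = 2)
  m <- fit_depth_polynomial(x, z)
  fit <- lm(z ~ x + I(x^2))          # independent oracle fit
  r2 <- 1 - sum(residuals(fit)^2) / sum((z - mean(z))^2)
  expect_equal(m$r_squared, r2, tolerance = 1e-10)
})

test_that("predict_depth evaluates the polynomial and clamps negatives", {
  m <- structure(list(coefficients = site_poly, degree = 2, n_points = 32,
                      r_squared = 0.91, residual_sd = 1),
                 class = "bathymetry_model")
  x1 <- matrix(1, 3, 3)
  expect_equal(predict_depth(m, x1)$values,
               matrix(24.135 - 70.038 + 51.571, 3, 3))   # 5.668 m
  expect_equal(predict_depth(m, matrix(0, 3, 3))$values[1, 1], 51.571)
  expect_equal(unique(as.vector(predict_depth(m, x1)$values)), 5.668)
  # constant field -> constant raster; negative predictions clamp to 0
  mneg <- structure(list(coefficients = c(0, 1, -3), degree = 2),
                    class = "bathymetry_model")
  out <- predict_depth(mneg, matrix(c(1, 5), 1, 2), scene_grid(1, 2))
  expect_equal(out$values, matrix(c(0, 2), 1, 2))
  expect_equal(attr(out, "n_clamped"), 1)
})

test_that("5x5 smoothing behaves like a uniform mask-aware filter", {
  z <- depth_raster(matrix(7, 20, 20))
  expect_equal(smooth_depth(z)$values, z$values)         # constant unchanged
  imp <- matrix(0, 21, 21); imp[11, 11] <- 25
  zi <- depth_raster(imp)
  sm <- smooth_depth(zi, 5)
  expect_equal(sm$values[11, 11], 1)                     # h / 25
  expect_equal(sm$values[11, 13], 1)
  expect_equal(sm$values[11, 14], 0)
  expect_true(sm$smoothed)
  # output bounded by input range (convexity of averaging)
  set.seed(3)
  zr <- depth_raster(matrix(runif(400, 2, 9), 20, 20))
  sr <- smooth_depth(zr)
  expect_gte(min(sr$values), min(zr$values))
  expect_lte(max(sr$values), max(zr$values))
  expect_error(smooth_depth(zr, 4), "odd")
  # masked pixels stay masked and do not contaminate neighbours
  mask <- matrix(FALSE, 20, 20); mask[5, 5] <- TRUE
  vals <- matrix(4, 20, 20); vals[5, 5] <- 1e6
  zm <- depth_raster(vals * !mask, mask = mask)
  smm <- smooth_depth(zm)
  expect_true(smm$mask[5, 5])
  expect_equal(smm$values[5, 7], 4)
})

test_that("validate_depth reports r-squared and RMSE against points", {
  g <- scene_grid(10, 10, 5)
  z <- depth_raster(matrix(seq(1, 10, length.out = 100), 10, 10), g)
  cc <- cell_center(g, c(2, 5, 8), c(3, 4, 9))
  obs <- z$values[cbind(c(2, 5, 8), c(3, 4, 9))]
  pts <- data.frame(x = cc$x, y = cc$y, depth_m = obs)
  v <- validate_depth(z, pts)
  expect_equal(v$r_squared, 1)
  expect_equal(v$rmse_m, 0)
  expect_equal(v$n, 3)
  # constant bias b: RMSE = |b|, r^2 stays 1
  pts_b <- pts; pts_b$depth_m <- obs + 1.7
  vb <- validate_depth(z, pts_b)
  expect_equal(vb$rmse_m, 1.7)
  expect_equal(vb$r_squared, 1)
  expect_error(validate_depth(z, pts[0, ]), "points")
})

test_that("end-to-end bathymetry on a clean scene tracks the truth", {
  # noise-free world: only the bottom-type ratio spread perturbs the fit
  sc <- clean_scene()
  rrs <- surface_to_rrs(sc$surface, optical_constants())
  est <- estimate_bathymetry(rrs, sc$depth_points[1:32, ])
  expect_s3_class(est$model, "bathymetry_model")
  expect_true(est$depth$smoothed)
  v <- validate_depth(est$depth, sc$depth_points[33:46, ])
  expect_gt(v$r_squared, 0.5)
  expect_lt(v$rmse_m, 5)
})
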