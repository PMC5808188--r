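#' Band log-ratio field
#'
#' Per-pixel `x = ln(Rrs(num) / Rrs(den))`. The ratio of two weakly
#' attenuated bands varies with depth but is comparatively insensitive to
#' the bottom type, which is what makes a site-calibrated polynomial in `x`
#' a workable depth estimator. Pixels where either band is non-positive (no
#' valid ratio) are set to `NA` and counted, not fatal.
#'
#' @param rrs a [reflectance_scene()] with stage `"Rrs"`.
#' @param num_band,den_band numerator / denominator wavelengths in nm
#'   (defaults 475 and 555: blue over green).
#' @return numeric matrix of log-ratios, `NA` where masked or invalid;
#'   attribute `n_invalid` counts newly invalid pixels.
#' @export
log_ratio <- function(rrs, num_band = 475, den_band = 555) {
  if (rrs$stage != "Rrs")
    stop("log_ratio expects an Rrs scene, got stage ", rrs$stage)
  num <- band_values(rrs, num_band)
  den <- band_values(rrs, den_band)
  ok <- !rrs$mask & num > 0 & den > 0
  x <- matrix(NA_real_, rrs$grid$rows, rrs$grid$cols)
  x[ok] <- log(num[ok] / den[ok])
  structure(x, n_invalid = sum(!ok & !rrs$mask))
}

#' Fit the depth-vs-log-ratio polynomial
#'
#' Ordinary least squares fit of `Z = a2*x^2 + a1*x + a0` (default degree 2)
#' to calibration points of known depth. Returns the fitted model with
#' diagnostics: `r_squared = 1 - SS_res/SS_tot` and the residual standard
#' deviation `sqrt(SS_res / (n - p))`.
#'
#' @param x log-ratio values at the calibration points.
#' @param depth_m in-situ depths (m) at the same points.
#' @param degree polynomial degree, default 2.
#' @return object of class `bathymetry_model` with fields `coefficients`
#'   (highest degree first, i.e. `c(a2, a1, a0)` for degree 2), `degree`,
#'   `n_points`, `r_squared`, `residual_sd`.
#' @export
fit_depth_polynomial <- function(x, depth_m, degree = 2) {
  stopifnot(length(x) == length(depth_m))
  ok <- is.finite(x) & is.finite(depth_m)
  x <- x[ok]; depth_m <- depth_m[ok]
  n <- length(x)
  if (n < degree + 1) stop("need at least degree+1 calibration points")
  if (length(unique(x)) < degree + 1)
    stop("rank-deficient calibration: too few distinct log-ratio values")
  X <- outer(x, degree:0, `^`)
  fit <- stats::lm.fit(X, depth_m)
  coefs <- fit$coefficients
  res <- fit$residuals
  ss_res <- sum(res^2)
  ss_tot <- sum((depth_m - mean(depth_m))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  dof <- n - (degree + 1)
  structure(list(coefficients = unname(coefs), degree = degree,
                 n_points = n,
                 r_squared = r2,
                 residual_sd = if (dof > 0) sqrt(ss_res / dof) else 0),
            class = "bathymetry_model")
}

#' @export
print.bathymetry_model <- function(x, ...) {
  terms <- paste(sprintf("%+.6g*x^%d", x$coefficients,
                         x$degree:0), collapse = " ")
  cat(sprintf("<bathymetry_model> Z = %s\n  n = %d, r^2 = %.4f, residual SD = %.3f m\n",
              terms, x$n_points, x$r_squared, x$residual_sd))
  invisible(x)
}

# polynomial evaluation, highest degree first
eval_poly <- function(coefs, x) {
  z <- 0
  for (c_i in coefs) z <- z * x + c_i
  z
}

#' Predict per-pixel depth from a ratio field
#'
#' Applies the calibrated polynomial to every valid log-ratio pixel.
#' Negative depth predictions are clamped to 0 and counted (attribute
#' `n_clamped`); `NA` ratio pixels become masked.
#'
#' @param model a [bathymetry_model()].
#' @param ratio log-ratio matrix from [log_ratio()].
#' @param grid the [scene_grid()] of the ratio field.
#' @return a [depth_raster()] (unsmoothed).
#' @export
predict_depth <- function(model, ratio, grid = NULL) {
  stopifnot(inherits(model, "bathymetry_model"))
  if (is.null(grid)) grid <- scene_grid(nrow(ratio), ncol(ratio))
  z <- eval_poly(model$coefficients, ratio)
  mask <- !is.finite(z)
  n_clamped <- sum(z < 0, na.rm = TRUE)
  z[!mask & z < 0] <- 0
  z[mask] <- 0
  out <- depth_raster(z, grid, mask)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Low-pass (moving average) depth smoothing
#'
#' Uniform window filter (default 5x5) to suppress pixel-scale noise before
#' water-column correction. Averaging is mask-aware: each output pixel is
#' the mean of the unmasked pixels in its window; masked pixels stay
#' masked. Edges use reflect padding so the map does not shrink.
#'
#' @param depth a [depth_raster()].
#' @param window odd window size >= 3, default 5.
#' @return a smoothed [depth_raster()] (`smoothed = TRUE`).
#' @export
smooth_depth <- function(depth, window = 5) {
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  h <- (window - 1L) / 2L
  v <- depth$values
  ok <- !depth$mask
  v[!ok] <- 0
  nr <- nrow(v); nc <- ncol(v)
  # reflect-pad index vectors (edge rows/cols mirrored without repeating edge)
  ridx <- reflect_index(nr, h)
  cidx <- reflect_index(nc, h)
  vp <- v[ridx, cidx, drop = FALSE]
  okp <- matrix(0, nr + 2 * h, nc + 2 * h)
  okp[] <- as.numeric(ok[ridx, cidx])
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (dr in 0:(window - 1L)) {
    for (dc in 0:(window - 1L)) {
      acc <- acc + vp[dr + seq_len(nr), dc + seq_len(nc)] *
        okp[dr + seq_len(nr), dc + seq_len(nc)]
      cnt <- cnt + okp[dr + seq_len(nr), dc + seq_len(nc)]
    }
  }
  out <- acc / pmax(cnt, 1)
  out[!ok] <- 0
  depth_raster(out, depth$grid, depth$mask, smoothed = TRUE)
}

reflect_index <- function(n, h) {
  if (n == 1L) return(rep(1L, 1L + 2 * h))
  left <- pmin(pmax(seq(h + 1, 2, by = -1), 1L), n)
  right <- pmin(pmax(seq(n - 1, n - h, by = -1), 1L), n)
  c(left, seq_len(n), right)
}

#' Validate predicted depth against in-situ points
#'
#' Looks up the predicted raster at each point (nearest pixel center,
#' half-open boundaries), then reports the squared correlation (OLS
#' `r^2`) of predicted vs observed depth and the RMSE of the differences.
#' Points on masked or out-of-grid pixels are dropped.
#'
#' @param predicted a [depth_raster()].
#' @param points data.frame with columns `x`, `y`, `depth_m`.
#' @return list with `r_squared`, `rmse_m`, `n`.
#' @export
validate_depth <- function(predicted, points) {
  rc <- lookup_cells(predicted$grid, points$x, points$y)
  ok <- !is.na(rc[, 1])
  ok[ok] <- !predicted$mask[rc[ok, , drop = FALSE]]
  if (sum(ok) < 2) stop("need >= 2 validation points on unmasked pixels")
  pred <- predicted$values[rc[ok, , drop = FALSE]]
  obs <- points$depth_m[ok]
  rmse <- sqrt(mean((pred - obs)^2))
  r2 <- if (stats::sd(pred) > 0 && stats::sd(obs) > 0)
    stats::cor(pred, obs)^2 else NA_real_
  list(r_squared = r2, rmse_m = rmse, n = sum(ok))
}

#' Calibrate bathymetry from a scene and depth points
#'
#' Convenience wrapper for the full satellite-derived-bathymetry chain on
#' one scene: log-ratio field, polynomial fit at the calibration points,
#' per-pixel prediction, and low-pass smoothing.
#'
#' @param rrs a [reflectance_scene()] at stage `"Rrs"`.
#' @param calib_points data.frame `x`, `y`, `depth_m`.
#' @param num_band,den_band ratio bands (nm), defaults 475/555.
#' @param degree polynomial degree, default 2.
#' @param window smoothing window (odd, default 5); `NULL` to skip.
#' @return list with `model` ([bathymetry_model()]) and `depth`
#'   (smoothed [depth_raster()]).
#' @export
estimate_bathymetry <- function(rrs, calib_points, num_band = 475,
                                den_band = 555, degree = 2, window = 5) {
  ratio <- log_ratio(rrs, num_band, den_band)
  rc <- lookup_cells(rrs$grid, calib_points$x, calib_points$y)
  ok <- !is.na(rc[, 1])
  xs <- rep(NA_real_, nrow(calib_points))
  xs[ok] <- ratio[rc[ok, , drop = FALSE]]
  model <- fit_depth_polynomial(xs, calib_points$depth_m, degree = degree)
  model$bands <- c(num = num_band, den = den_band)
  z <- predict_depth(model, ratio, rrs$grid)
  if (!is.null(window)) z <- smooth_depth(z, window)
  list(model = model, depth = z)
}

#' Serialize a bathymetry model to JSON
#' @param model a [bathymetry_model()].
#' @param path output JSON path.
#' @return `path` invisibly; `read_bathymetry_model` returns the model.
#' @export
write_bathymetry_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_bathymetry_model
#' @export
read_bathymetry_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "bathymetry_model")
}
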