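#' Per-band optical constants for the shallow-water model
#'
#' Bundles the quantities the analytical water-column model needs: the
#' operational diffuse attenuation coefficient `Kd` (m^-1) of the combined
#' up- and down-welling streams, the infinitely-deep-column reflectance
#' `R_inf` per band, the air-water transmittance factor `t`, and the
#' upwelling irradiance-to-radiance ratio `Q` (sr). Defaults are the
#' operational values for a NW Aegean coastal site at the three usable
#' visible bands (475/555/658 nm): `Kd = (0.067, 0.078, 0.134)` m^-1 and
#' `R_inf = (0.033, 0.024, 0.017)`, with `t = 0.54` and `Q = pi` (the
#' theoretical Lambertian value).
#'
#' @param bands band center wavelengths (nm).
#' @param Kd per-band attenuation coefficient (m^-1), all > 0.
#' @param R_inf per-band deep-column reflectance, in `[0, 1)`.
#' @param t air-water transmittance, in `(0, 1]`.
#' @param Q irradiance-to-radiance ratio (sr), > 0.
#' @return object of class `optical_constants`.
#' @export
optical_constants <- function(bands = c(475, 555, 658),
                              Kd = c(0.067, 0.078, 0.134),
                              R_inf = c(0.033, 0.024, 0.017),
                              t = 0.54, Q = pi) {
  if (length(bands) != length(Kd) || length(bands) != length(R_inf))
    stop("bands, Kd and R_inf must have equal length")
  if (any(Kd <= 0)) stop("Kd must be > 0 per band")
  if (any(R_inf < 0 | R_inf >= 1)) stop("R_inf must be in [0, 1) per band")
  if (t <= 0 || t > 1) stop("t must be in (0, 1]")
  if (Q <= 0) stop("Q must be > 0")
  structure(list(bands = as.numeric(bands), Kd = as.numeric(Kd),
                 R_inf = as.numeric(R_inf), t = t, Q = Q),
            class = "optical_constants")
}

#' @export
print.optical_constants <- function(x, ...) {
  cat("<optical_constants>\n")
  print(data.frame(band_nm = x$bands, Kd = x$Kd, R_inf = x$R_inf))
  cat(sprintf("t = %g, Q = %g sr\n", x$t, x$Q))
  invisible(x)
}

match_optics <- function(scene, optics) {
  idx <- match(scene$bands, optics$bands)
  if (any(is.na(idx)))
    stop("optical constants missing for band(s) ",
         paste(scene$bands[is.na(idx)], collapse = ", "), " nm")
  idx
}

#' Convert at-surface reflectance to remote-sensing reflectance
#'
#' Applies the linear radiometric conversion `Rrs = t * R / Q` per pixel and
#' band. `Rrs` is less sensitive to air-water interface effects and is the
#' input to band-ratio bathymetry.
#'
#' @param scene a [reflectance_scene()] with stage `"surface_R"`.
#' @param optics an [optical_constants()].
#' @return a [reflectance_scene()] with stage `"Rrs"`; mask unchanged.
#' @export
surface_to_rrs <- function(scene, optics) {
  if (scene$stage != "surface_R")
    stop("surface_to_rrs expects a surface_R scene, got stage ", scene$stage)
  out <- scene
  out$values <- scene$values * (optics$t / optics$Q)
  out$stage <- "Rrs"
  out
}

#' Estimate deep-column reflectance from a deep-water polygon
#'
#' Per-band arithmetic mean of the unmasked at-surface reflectance pixels
#' whose centers fall inside the polygon. This is the image-based estimator
#' of the model asymptote `R_inf`.
#'
#' @param scene a [reflectance_scene()] (stage `"surface_R"`).
#' @param polygon two-column vertex matrix (see [read_polygon()]).
#' @return list with `R_inf` (named per-band means), `n_pixels` used.
#' @export
estimate_deep_reflectance <- function(scene, polygon) {
  g <- scene$grid
  cc <- cell_center(g, row = rep(seq_len(g$rows), times = g$cols),
                    col = rep(seq_len(g$cols), each = g$rows))
  inside <- matrix(point_in_polygon(cc$x, cc$y, polygon), g$rows, g$cols)
  use <- inside & !scene$mask
  n <- sum(use)
  if (n == 0L) stop("deep-water polygon contains no unmasked pixels")
  r <- vapply(seq_along(scene$bands),
              function(k) mean(scene$values[, , k][use]), numeric(1))
  names(r) <- paste0("b", scene$bands)
  list(R_inf = r, n_pixels = n)
}

#' Forward shallow-water reflectance model
#'
#' Evaluates, per pixel and band, the analytical optically-shallow model
#' `R = R_inf + (Rb - R_inf) * exp(-2 * Kd * Z)`: the surface signal decays
#' exponentially from the bottom reflectance toward the deep-column
#' asymptote as depth grows.
#'
#' @param bottom a [reflectance_scene()] with stage `"bottom_Rb"`.
#' @param depth a [depth_raster()] on the same grid, depths >= 0.
#' @param optics an [optical_constants()].
#' @return a [reflectance_scene()] with stage `"surface_R"`; mask is the
#'   union of the input masks.
#' @export
forward_shallow_reflectance <- function(bottom, depth, optics) {
  if (bottom$stage != "bottom_Rb")
    stop("forward model expects a bottom_Rb scene, got stage ", bottom$stage)
  stop_if_grid_mismatch(bottom$grid, depth$grid, "bottom and depth")
  if (any(!depth$mask & depth$values < 0)) stop("negative depth")
  idx <- match_optics(bottom, optics)
  out <- bottom
  for (k in seq_along(bottom$bands)) {
    Rinf <- optics$R_inf[idx[k]]
    att <- exp(-2 * optics$Kd[idx[k]] * depth$values)
    out$values[, , k] <- Rinf + (bottom$values[, , k] - Rinf) * att
  }
  out$mask <- bottom$mask | depth$mask
  out$values[is.na(out$values)] <- 0
  out$stage <- "surface_R"
  out
}

#' Invert the water column: surface to bottom reflectance
#'
#' Algebraic inverse of the shallow-water model:
#' `Rb = R_inf + (R - R_inf) * exp(+2 * Kd * Z)`. Because the correction
#' amplifies exponentially with depth, apply [apply_deep_mask()] first so
#' optically deep pixels never enter the inversion. Values falling outside
#' `[0, 1]` are counted and, per `out_of_range`, clamped (default) or
#' masked.
#'
#' @param surface a [reflectance_scene()] with stage `"surface_R"`.
#' @param depth a [depth_raster()] on the same grid.
#' @param optics an [optical_constants()].
#' @param out_of_range `"clamp"` (default) or `"mask"`.
#' @return a [reflectance_scene()] with stage `"bottom_Rb"`; attribute
#'   `n_out_of_range` counts flagged pixels.
#' @export
correct_water_column <- function(surface, depth, optics,
                                 out_of_range = c("clamp", "mask")) {
  out_of_range <- match.arg(out_of_range)
  if (surface$stage != "surface_R")
    stop("correct_water_column expects a surface_R scene, got stage ",
         surface$stage)
  stop_if_grid_mismatch(surface$grid, depth$grid, "surface and depth")
  if (any(!surface$mask & depth$mask))
    stop("missing depth at unmasked reflectance pixel")
  idx <- match_optics(surface, optics)
  out <- surface
  flagged <- matrix(FALSE, surface$grid$rows, surface$grid$cols)
  for (k in seq_along(surface$bands)) {
    Rinf <- optics$R_inf[idx[k]]
    amp <- exp(2 * optics$Kd[idx[k]] * depth$values)
    rb <- Rinf + (surface$values[, , k] - Rinf) * amp
    flagged <- flagged | (!surface$mask & (rb < 0 | rb > 1))
    if (out_of_range == "clamp") rb <- pmin(pmax(rb, 0), 1)
    out$values[, , k] <- rb
  }
  out$mask <- surface$mask | depth$mask
  if (out_of_range == "mask") out$mask <- out$mask | flagged
  out$values[is.na(out$values) | array(out$mask, dim(out$values))] <- 0
  out$stage <- "bottom_Rb"
  attr(out, "n_out_of_range") <- sum(flagged)
  out
}

#' Mask optically deep water
#'
#' Pixels deeper than `limit_m` (or with nodata depth) carry no measurable
#' bottom signal; they are masked out before inversion and classification.
#' The operational optically-deep limit for the site is 16.5 m.
#'
#' @param scene a [reflectance_scene()].
#' @param depth a [depth_raster()] on the same grid.
#' @param limit_m depth limit in metres (> 0), default 16.5.
#' @return the scene with the deep mask OR-ed into its nodata mask; values
#'   at surviving pixels unchanged.
#' @export
apply_deep_mask <- function(scene, depth, limit_m = 16.5) {
  if (!is.numeric(limit_m) || limit_m <= 0) stop("limit_m must be > 0")
  stop_if_grid_mismatch(scene$grid, depth$grid, "scene and depth")
  deep <- depth$mask | depth$values > limit_m
  out <- scene
  out$mask <- scene$mask | deep
  out
}
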