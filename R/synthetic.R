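#' Specification of a synthetic coastal scene
#'
#' Describes the world the generator emulates: a shore-to-deep depth
#' gradient (default 0.8-18.9 m), four benthic classes with distinct 3-band
#' bottom spectra, water-column attenuation with the operational optical
#' constants, additive Gaussian sensor noise, and 50 training plus 50
#' validation ground-truth points per class.
#'
#' Default class spectra (bands 475/555/658 nm): sand (0.20, 0.18, 0.12) is
#' brightest; rocky algae (0.08, 0.10, 0.05); C. nodosa (0.06, 0.08, 0.04)
#' intermediate and sand-mixed; P. oceanica (0.03, 0.05, 0.02) darkest -
#' dark enough that its shallow pixels can look "deeper" than sand at the
#' same true depth, as dense canopies do. The spectra are plausible
#' stand-ins, not site-calibrated measurements.
#'
#' Classes carry depth affinities mirroring the reported mean depths of
#' presence (C. nodosa ~5.8 m, P. oceanica ~8 m), rocky algae prefer the
#' shallows and sand is depth-neutral.
#'
#' @param rows,cols grid size in pixels (default 200 x 200).
#' @param pixel_size pixel side in metres (default 5).
#' @param depth_range `c(min, max)` depth in metres, default `c(0.8, 18.9)`.
#' @param class_means 4 x n_bands matrix of mean bottom reflectance.
#' @param class_sd within-class spectral standard deviation per class.
#' @param sensor_noise_sd additive Gaussian noise SD in reflectance units,
#'   default 0.002.
#' @param optics an [optical_constants()].
#' @param n_points_per_class_train,n_points_per_class_val default 50 each.
#' @param n_depth_points number of in-situ style depth points, default 46
#'   (32 calibration + 14 validation when split 32/14 by the caller).
#' @param class_prior relative prior weight per class (default equal); a
#'   prior of 1 for one class with 0 elsewhere yields a single-class map.
#' @param geographic_split if `TRUE`, training points are drawn from the
#'   left half of the grid and validation points from the right half,
#'   mimicking a spatially disjoint train/validate layout.
#' @param rng_seed integer seed; the whole scene is bit-reproducible.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(rows = 200, cols = 200, pixel_size = 5,
                       depth_range = c(0.8, 18.9),
                       class_means = default_class_means(),
                       class_sd = rep(0.005, 4),
                       sensor_noise_sd = 0.002,
                       optics = optical_constants(),
                       n_points_per_class_train = 50,
                       n_points_per_class_val = 50,
                       n_depth_points = 46,
                       class_prior = rep(1, 4) / 4,
                       geographic_split = FALSE,
                       rng_seed = 42L) {
  class_means <- as.matrix(class_means)
  if (nrow(class_means) != 4) stop("exactly 4 benthic classes are modelled")
  if (ncol(class_means) != length(optics$bands))
    stop("class_means columns must match optics bands")
  if (any(class_means < 0 | class_means > 1) || any(class_sd < 0 | class_sd > 1))
    stop("reflectance means and deviations must lie in [0, 1]")
  for (i in 1:3) for (j in (i + 1):4)
    if (all(class_means[i, ] == class_means[j, ]))
      stop("class means must be pairwise distinct in at least one band")
  if (depth_range[1] > depth_range[2] || any(depth_range < 0))
    stop("depth_range must satisfy 0 <= min <= max")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (length(class_prior) != 4 || any(class_prior < 0) || sum(class_prior) == 0)
    stop("class_prior must be 4 non-negative weights, not all zero")
  structure(list(grid = scene_grid(rows, cols, pixel_size),
                 depth_range = as.numeric(depth_range),
                 class_means = class_means, class_sd = as.numeric(class_sd),
                 sensor_noise_sd = sensor_noise_sd, optics = optics,
                 n_train = as.integer(n_points_per_class_train),
                 n_val = as.integer(n_points_per_class_val),
                 n_depth_points = as.integer(n_depth_points),
                 class_prior = class_prior / sum(class_prior),
                 geographic_split = isTRUE(geographic_split),
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @export
default_class_means <- function() {
  m <- rbind(`C. nodosa`    = c(0.06, 0.08, 0.04),
             `P. oceanica`  = c(0.03, 0.05, 0.02),
             `rocky algae`  = c(0.08, 0.10, 0.05),
             sand           = c(0.20, 0.18, 0.12))
  colnames(m) <- c("b475", "b555", "b658")
  m
}

# spatially correlated unit-variance noise field: smoothed white noise
correlated_field <- function(rows, cols, smooth_window = 9, passes = 2) {
  m <- matrix(stats::rnorm(rows * cols), rows, cols)
  for (p in seq_len(passes)) m <- box_blur(m, smooth_window)
  s <- stats::sd(as.vector(m))
  if (s > 0) m <- m / s
  m
}

box_blur <- function(m, window) {
  h <- (window - 1L) %/% 2L
  ridx <- reflect_index(nrow(m), h)
  cidx <- reflect_index(ncol(m), h)
  mp <- m[ridx, cidx, drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (dr in 0:(window - 1L)) for (dc in 0:(window - 1L))
    out <- out + mp[dr + seq_len(nrow(m)), dc + seq_len(ncol(m))]
  out / window^2
}

#' Generate the synthetic depth surface
#'
#' A smooth shore-to-deep gradient (shallow at the left edge, deep at the
#' right) plus low-amplitude spatially correlated noise, clamped to the
#' spec's depth range. Deterministic under the spec seed.
#'
#' @param spec a [scene_spec()].
#' @return a [depth_raster()].
#' @export
generate_depth_surface <- function(spec) {
  g <- spec$grid
  if (g$rows < 5 || g$cols < 5) stop("degenerate grid: need at least 5 x 5")
  zmin <- spec$depth_range[1]; zmax <- spec$depth_range[2]
  if (zmin == zmax)
    return(depth_raster(matrix(zmin, g$rows, g$cols), g))
  set.seed(spec$rng_seed)
  ramp <- matrix(rep(seq(zmin, zmax, length.out = g$cols), each = g$rows),
                 g$rows, g$cols)
  noise <- correlated_field(g$rows, g$cols) * 0.05 * (zmax - zmin)
  z <- pmin(pmax(ramp + noise, zmin), zmax)
  depth_raster(z, g)
}

#' Generate the synthetic habitat map
#'
#' Contiguous class patches from smoothed categorical noise: each class
#' scores a depth-affinity term plus a spatially correlated noise field
#' plus its log prior; the arg-max class wins each pixel. Errors if any
#' class cannot supply the requested ground-truth points.
#'
#' @param spec a [scene_spec()].
#' @param depth a [depth_raster()] on the spec grid.
#' @return a [habitat_map()].
#' @export
generate_habitat_map <- function(spec, depth) {
  g <- spec$grid
  stop_if_grid_mismatch(g, depth$grid, "spec grid and depth")
  set.seed(spec$rng_seed + 1L)
  # depth preference (mean presence depth, spread) per class; sand is neutral
  aff <- list(`1` = c(5.8, 3.5), `2` = c(8, 4.5), `3` = c(3, 3.5), `4` = NULL)
  score <- array(0, dim = c(g$rows, g$cols, 4))
  for (k in 1:4) {
    a <- aff[[k]]
    base <- if (is.null(a)) 0.5
            else exp(-((depth$values - a[1])^2) / (2 * a[2]^2))
    lp <- if (spec$class_prior[k] > 0) log(spec$class_prior[k]) else -Inf
    score[, , k] <- base + 0.6 * correlated_field(g$rows, g$cols) + lp
  }
  # vectorized arg-max; ties go to the lowest class code
  lab <- matrix(1L, g$rows, g$cols)
  best <- score[, , 1]
  for (k in 2:4) {
    upd <- score[, , k] > best
    lab[upd] <- k
    best[upd] <- score[, , k][upd]
  }
  need <- spec$n_train + spec$n_val
  counts <- tabulate(lab, nbins = 4)
  live <- which(spec$class_prior > 0)
  if (any(counts[live] < need))
    stop("class(es) ", paste(live[counts[live] < need], collapse = ", "),
         " cannot supply ", need, " ground-truth points")
  habitat_map(matrix(as.integer(lab), g$rows, g$cols), g)
}

#' Render surface reflectance and sample ground truth
#'
#' Draws per-pixel bottom reflectance from the class spectra (mean plus
#' truncated Gaussian within-class deviation), pushes it through the
#' forward shallow-water model, adds independent Gaussian sensor noise,
#' clips to `[0, 1]`, and samples disjoint train/validation habitat points
#' and depth points from the truth rasters.
#'
#' @param habitat a [habitat_map()].
#' @param depth a [depth_raster()] on the same grid.
#' @param spec the generating [scene_spec()].
#' @return object of class `synthetic_scene` with fields `truth_habitat`,
#'   `truth_depth`, `truth_bottom` (stage `bottom_Rb`), `surface` (stage
#'   `surface_R`), `train_points`, `val_points`, `depth_points`, `spec`.
#' @export
render_surface_reflectance <- function(habitat, depth, spec) {
  g <- spec$grid
  stop_if_grid_mismatch(habitat$grid, depth$grid, "habitat and depth")
  stop_if_grid_mismatch(habitat$grid, g, "habitat and spec grid")
  set.seed(spec$rng_seed + 2L)
  nb <- length(spec$optics$bands)
  rb <- array(0, dim = c(g$rows, g$cols, nb))
  for (k in 1:4) {
    pix <- habitat$values == k
    n_k <- sum(pix)
    if (!n_k) next
    for (b in seq_len(nb)) {
      draw <- spec$class_means[k, b] + spec$class_sd[k] * stats::rnorm(n_k)
      rb[, , b][pix] <- pmin(pmax(draw, 0), 1)  # truncation, not rejection
    }
  }
  bottom <- reflectance_scene(rb, bands = spec$optics$bands, grid = g,
                              stage = "bottom_Rb")
  surface <- forward_shallow_reflectance(bottom, depth, spec$optics)
  if (spec$sensor_noise_sd > 0) {
    surface$values <- surface$values +
      stats::rnorm(length(surface$values), sd = spec$sensor_noise_sd)
  }
  surface$values <- pmin(pmax(surface$values, 0), 1)

  pts <- sample_truth_points(habitat, spec)
  dp <- sample_depth_points(depth, spec)
  structure(list(truth_habitat = habitat, truth_depth = depth,
                 truth_bottom = bottom, surface = surface,
                 train_points = pts$train, val_points = pts$val,
                 depth_points = dp, spec = spec),
            class = "synthetic_scene")
}

# uniform without-replacement sampling inside class masks; train and val
# disjoint by construction (one draw, then split)
sample_truth_points <- function(habitat, spec) {
  g <- habitat$grid
  half <- ceiling(g$cols / 2)
  col_of <- function(cells) ((cells - 1L) %/% g$rows) + 1L
  train <- list(); val <- list()
  for (k in 1:4) {
    cells <- which(habitat$values == k)
    if (!length(cells)) next
    if (spec$geographic_split) {
      left <- cells[col_of(cells) <= half]
      right <- cells[col_of(cells) > half]
      if (length(left) < spec$n_train || length(right) < spec$n_val)
        stop("geographic split: class ", k, " lacks points in one half")
      tr <- sample(left, spec$n_train)
      va <- sample(right, spec$n_val)
    } else {
      need <- spec$n_train + spec$n_val
      if (length(cells) < need)
        stop("class ", k, " cannot supply ", need, " points")
      pick <- sample(cells, need)
      tr <- pick[seq_len(spec$n_train)]
      va <- pick[spec$n_train + seq_len(spec$n_val)]
    }
    train[[k]] <- cells_to_points(g, tr, k)
    val[[k]] <- cells_to_points(g, va, k)
  }
  list(train = do.call(rbind, train), val = do.call(rbind, val))
}

cells_to_points <- function(grid, cells, class_code) {
  row <- ((cells - 1L) %% grid$rows) + 1L
  col <- ((cells - 1L) %/% grid$rows) + 1L
  cc <- cell_center(grid, row, col)
  data.frame(x = cc$x, y = cc$y, class = class_code)
}

sample_depth_points <- function(depth, spec) {
  g <- depth$grid
  cells <- which(!depth$mask)
  pick <- sample(cells, min(spec$n_depth_points, length(cells)))
  row <- ((pick - 1L) %% g$rows) + 1L
  col <- ((pick - 1L) %/% g$rows) + 1L
  cc <- cell_center(g, row, col)
  data.frame(x = cc$x, y = cc$y, depth_m = depth$values[cbind(row, col)])
}

#' Generate a complete synthetic scene
#'
#' Runs [generate_depth_surface()], [generate_habitat_map()] and
#' [render_surface_reflectance()] in order. Bit-reproducible for a fixed
#' `rng_seed`.
#'
#' @param spec a [scene_spec()].
#' @return a `synthetic_scene` (see [render_surface_reflectance()]).
#' @export
simulate_scene <- function(spec) {
  depth <- generate_depth_surface(spec)
  habitat <- generate_habitat_map(spec, depth)
  render_surface_reflectance(habitat, depth, spec)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene>\n  "); print(x$truth_habitat)
  cat("  "); print(x$truth_depth)
  cat(sprintf("  %d train / %d val / %d depth points\n",
              nrow(x$train_points), nrow(x$val_points), nrow(x$depth_points)))
  invisible(x)
}

#' Write a synthetic scene to a directory
#'
#' Products: surface reflectance bands (`surface_b*.asc` + sidecar), truth
#' depth (`truth_depth.asc`), truth habitat (`truth_habitat.asc` + class
#' table sidecar), point CSVs, and a JSON manifest recording the spec and
#' seed.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_scene_dir <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_scene(scene$surface, file.path(dir, "surface"))
  write_depth(scene$truth_depth, file.path(dir, "truth_depth.asc"))
  write_habitat(scene$truth_habitat, file.path(dir, "truth_habitat.asc"))
  write_points_csv(scene$train_points, file.path(dir, "train_points.csv"))
  write_points_csv(scene$val_points, file.path(dir, "val_points.csv"))
  write_points_csv(scene$depth_points, file.path(dir, "depth_points.csv"))
  spec <- scene$spec
  manifest <- list(generator = "seagrassmapr::simulate_scene",
                   rng_seed = spec$rng_seed,
                   grid = spec$grid[c("rows", "cols", "pixel_size", "origin")],
                   depth_range = spec$depth_range,
                   class_means = spec$class_means,
                   class_sd = spec$class_sd,
                   sensor_noise_sd = spec$sensor_noise_sd,
                   optics = unclass(spec$optics),
                   n_points_per_class_train = spec$n_train,
                   n_points_per_class_val = spec$n_val,
                   n_depth_points = spec$n_depth_points,
                   class_prior = spec$class_prior,
                   geographic_split = spec$geographic_split,
                   classes = habitat_classes())
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(p)
}
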