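#' Scene grid geometry
#'
#' A `scene_grid` describes the affine geometry shared by every raster in a
#' scene: number of rows and columns, square pixel size in metres, and the
#' map coordinate of the top-left corner. Rows run north-to-south (row 1 is
#' the top edge), columns west-to-east, matching the usual raster layout.
#'
#' @param rows,cols positive integer raster dimensions.
#' @param pixel_size side of a (square) pixel in metres; default 5.
#' @param origin numeric length-2, map coordinate `(x, y)` of the top-left
#'   corner of pixel `[1, 1]`. Default `c(0, rows * pixel_size)` so that the
#'   bottom-left corner sits at the coordinate origin.
#' @return an object of class `scene_grid`.
#' @export
scene_grid <- function(rows, cols, pixel_size = 5, origin = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("grid must have at least one row and column")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (is.null(origin)) origin <- c(0, rows * pixel_size)
  stopifnot(is.numeric(origin), length(origin) == 2L)
  structure(list(rows = rows, cols = cols, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "scene_grid")
}

#' @export
print.scene_grid <- function(x, ...) {
  cat(sprintf("<scene_grid> %d x %d pixels, %.3g m/pixel, origin (%.6g, %.6g)\n",
              x$rows, x$cols, x$pixel_size, x$origin[1], x$origin[2]))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$rows == b$rows && a$cols == b$cols &&
    abs(a$pixel_size - b$pixel_size) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) {
    stop(sprintf("grid mismatch between %s: %dx%d @%.3g m vs %dx%d @%.3g m",
                 what, a$rows, a$cols, a$pixel_size, b$rows, b$cols, b$pixel_size),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Map coordinates of pixel centers
#'
#' @param grid a [scene_grid()].
#' @param row,col integer vectors of equal length (recycled).
#' @return data.frame with columns `x`, `y`.
#' @export
cell_center <- function(grid, row, col) {
  data.frame(x = grid$origin[1] + (col - 0.5) * grid$pixel_size,
             y = grid$origin[2] - (row - 0.5) * grid$pixel_size)
}

#' Locate points on the grid
#'
#' Nearest-pixel lookup with half-open pixel boundaries: a point on the
#' left/top edge of a pixel belongs to that pixel. Points outside the grid
#' get `NA` row/col.
#'
#' @param grid a [scene_grid()].
#' @param x,y point map coordinates.
#' @return data.frame with integer columns `row`, `col` (`NA` if outside).
#' @export
point_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$pixel_size) + 1
  row <- floor((grid$origin[2] - y) / grid$pixel_size) + 1
  # points exactly on the bottom/right boundary of the grid snap inward
  col[x == grid$origin[1] + grid$cols * grid$pixel_size] <- grid$cols
  row[y == grid$origin[2] - grid$rows * grid$pixel_size] <- grid$rows
  bad <- row < 1 | row > grid$rows | col < 1 | col > grid$cols | !is.finite(x) | !is.finite(y)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# ---------------------------------------------------------------------------
# Raster containers

#' Multiband reflectance scene
#'
#' Holds aligned per-band reflectance planes plus a nodata mask and a
#' processing-stage tag. The three stages mirror the pre-classification
#' chain: `"surface_R"` (at-water-surface reflectance, the pipeline entry
#' point), `"Rrs"` (remote-sensing reflectance), and `"bottom_Rb"`
#' (water-column-corrected bottom reflectance).
#'
#' @param values numeric array `rows x cols x n_bands`, unitless reflectance.
#' @param bands numeric vector of band center wavelengths in nm
#'   (default `c(475, 555, 658)`).
#' @param grid a [scene_grid()]; defaults to a grid matching `values`.
#' @param mask logical matrix, `TRUE` = nodata/masked (default none).
#' @param stage one of `"surface_R"`, `"Rrs"`, `"bottom_Rb"`.
#' @return object of class `reflectance_scene`.
#' @export
reflectance_scene <- function(values, bands = c(475, 555, 658), grid = NULL,
                              mask = NULL, stage = "surface_R") {
  stage <- match.arg(stage, c("surface_R", "Rrs", "bottom_Rb"))
  if (length(dim(values)) == 2L) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L)
  d <- dim(values)
  if (d[3] != length(bands)) stop("third dimension of values must match bands")
  if (is.null(grid)) grid <- scene_grid(d[1], d[2])
  if (d[1] != grid$rows || d[2] != grid$cols) stop("values do not match grid")
  if (is.null(mask)) mask <- matrix(FALSE, d[1], d[2])
  stopifnot(is.logical(mask), all(dim(mask) == d[1:2]))
  n_finite <- rowSums(is.finite(values), dims = 2)
  if (any(!mask & n_finite < d[3]))
    stop("non-finite reflectance at unmasked pixels")
  structure(list(values = values, bands = as.numeric(bands), grid = grid,
                 mask = mask, stage = stage),
            class = "reflectance_scene")
}

#' @export
print.reflectance_scene <- function(x, ...) {
  cat(sprintf("<reflectance_scene stage=%s> bands %s nm, %d x %d px (%d masked)\n",
              x$stage, paste(x$bands, collapse = "/"),
              x$grid$rows, x$grid$cols, sum(x$mask)))
  invisible(x)
}

band_index <- function(scene, band_nm) {
  i <- match(band_nm, scene$bands)
  if (is.na(i)) stop(sprintf("band %s nm not present (have %s)", band_nm,
                             paste(scene$bands, collapse = ", ")))
  i
}

band_values <- function(scene, band_nm) scene$values[, , band_index(scene, band_nm)]

#' Per-pixel water depth raster
#'
#' Depth in metres, positive downward; unmasked values must be >= 0.
#'
#' @param values numeric matrix of depths (m).
#' @param grid a [scene_grid()] (default inferred from `values`).
#' @param mask logical nodata mask.
#' @param smoothed has a low-pass filter been applied?
#' @return object of class `depth_raster`.
#' @export
depth_raster <- function(values, grid = NULL, mask = NULL, smoothed = FALSE) {
  stopifnot(is.matrix(values))
  if (is.null(grid)) grid <- scene_grid(nrow(values), ncol(values))
  if (nrow(values) != grid$rows || ncol(values) != grid$cols)
    stop("values do not match grid")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(values), ncol(values))
  if (any(!mask & (!is.finite(values) | values < 0)))
    stop("unmasked depths must be finite and >= 0")
  structure(list(values = values, grid = grid, mask = mask,
                 smoothed = isTRUE(smoothed)),
            class = "depth_raster")
}

#' @export
print.depth_raster <- function(x, ...) {
  v <- x$values[!x$mask]
  cat(sprintf("<depth_raster%s> %d x %d px, depth %.2f-%.2f m (%d masked)\n",
              if (x$smoothed) " smoothed" else "", x$grid$rows, x$grid$cols,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(x$mask)))
  invisible(x)
}

#' Benthic class code table
#'
#' Fixed four-class legend used throughout: 1 = Cymodocea nodosa,
#' 2 = Posidonia oceanica, 3 = rocky algae, 4 = sand; 0 = nodata/masked.
#'
#' @return data.frame with columns `code`, `label`.
#' @export
habitat_classes <- function() {
  data.frame(code = 1:4,
             label = c("C. nodosa", "P. oceanica", "rocky algae", "sand"),
             stringsAsFactors = FALSE)
}

#' Categorical habitat map
#'
#' @param values integer matrix with values in `0:4` (0 = masked/nodata).
#' @param grid a [scene_grid()].
#' @param classes class code table; default [habitat_classes()].
#' @return object of class `habitat_map`.
#' @export
habitat_map <- function(values, grid = NULL, classes = habitat_classes()) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "integer"
  if (is.null(grid)) grid <- scene_grid(nrow(values), ncol(values))
  if (nrow(values) != grid$rows || ncol(values) != grid$cols)
    stop("values do not match grid")
  if (!all(values %in% c(0L, classes$code)))
    stop("habitat codes must be 0 (masked) or listed in the class table")
  structure(list(values = values, grid = grid, classes = classes),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  tab <- tabulate(x$values + 1L, nbins = max(x$classes$code) + 1L)
  cat(sprintf("<habitat_map> %d x %d px; masked=%d; %s\n",
              x$grid$rows, x$grid$cols, tab[1],
              paste(sprintf("%s=%d", x$classes$label, tab[-1]), collapse = ", ")))
  invisible(x)
}

# value lookup at point coordinates; returns NA outside grid
lookup_cells <- function(grid, x, y) {
  rc <- point_to_cell(grid, x, y)
  cbind(rc$row, rc$col)
}
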