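#' Raster, point, polygon and config I/O
#'
#' Rasters are stored in the Esri ASCII grid format (`.asc`): a plain-text
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values from the top row down. The
#' format is text-only yet readable by GDAL/QGIS, and preserves the affine
#' grid and nodata exactly. Multiband scenes are written as one `.asc` per
#' band plus a JSON sidecar recording bands, stage and (for habitat maps)
#' the class code table.
#'
#' @name raster_io
NULL

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a single-band ASCII grid
#' @param values numeric matrix.
#' @param grid a [scene_grid()].
#' @param path output file path.
#' @param mask logical nodata mask (TRUE = nodata).
#' @param nodata nodata sentinel written to file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path, mask = NULL, nodata = -9999) {
  if (is.null(mask)) mask <- matrix(FALSE, nrow(values), ncol(values))
  v <- values
  v[mask] <- nodata
  yll <- grid$origin[2] - grid$rows * grid$pixel_size
  hdr <- c(paste("ncols", grid$cols),
           paste("nrows", grid$rows),
           paste("xllcorner", fmt_num(grid$origin[1])),
           paste("yllcorner", fmt_num(yll)),
           paste("cellsize", fmt_num(grid$pixel_size)),
           paste("NODATA_value", fmt_num(nodata)))
  body <- apply(v, 1L, function(r) paste(fmt_num(r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a single-band ASCII grid
#' @param path `.asc` file path.
#' @return list with `values` (matrix, `NA` at nodata), `grid`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header in ", path)
  rows <- as.integer(hdr$nrows); cols <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != rows * cols) stop("ASCII grid body size mismatch in ", path)
  m <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA_real_
  grid <- scene_grid(rows, cols, hdr$cellsize,
                     origin = c(hdr$xllcorner, hdr$yllcorner + rows * hdr$cellsize))
  list(values = m, grid = grid, nodata = nodata)
}

#' Write / read a multiband reflectance scene
#'
#' Writes `<stem>_b<band>.asc` per band and `<stem>.json` (bands, stage).
#' @param scene a [reflectance_scene()].
#' @param stem path stem (no extension).
#' @return the sidecar path, invisibly.
#' @export
write_scene <- function(scene, stem) {
  paths <- character(0)
  for (k in seq_along(scene$bands)) {
    p <- sprintf("%s_b%g.asc", stem, scene$bands[k])
    write_ascii_grid(scene$values[, , k], scene$grid, p, mask = scene$mask)
    paths <- c(paths, basename(p))
  }
  meta <- list(type = "reflectance_scene", stage = scene$stage,
               bands = scene$bands, files = paths)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(stem, ".json"))
}

#' @rdname write_scene
#' @export
read_scene <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  dirn <- dirname(stem)
  layers <- lapply(file.path(dirn, meta$files), read_ascii_grid)
  g <- layers[[1]]$grid
  arr <- array(NA_real_, dim = c(g$rows, g$cols, length(layers)))
  mask <- is.na(layers[[1]]$values)
  for (k in seq_along(layers)) {
    stop_if_grid_mismatch(g, layers[[k]]$grid, "scene bands")
    arr[, , k] <- layers[[k]]$values
    mask <- mask | is.na(layers[[k]]$values)
  }
  arr[is.na(arr)] <- 0
  reflectance_scene(arr, bands = meta$bands, grid = g, mask = mask,
                    stage = meta$stage)
}

#' Write / read a depth raster
#' @param depth a [depth_raster()].
#' @param path `.asc` file path.
#' @return `path` invisibly; `read_depth` returns a [depth_raster()].
#' @export
write_depth <- function(depth, path) {
  write_ascii_grid(depth$values, depth$grid, path, mask = depth$mask)
}

#' @rdname write_depth
#' @export
read_depth <- function(path) {
  g <- read_ascii_grid(path)
  mask <- is.na(g$values)
  g$values[mask] <- 0
  depth_raster(g$values, g$grid, mask)
}

#' Write / read a habitat label map
#'
#' The class code table travels in a `<path>.classes.json` sidecar so the
#' legend survives a round trip.
#' @param map a [habitat_map()].
#' @param path `.asc` file path.
#' @return `path` invisibly; `read_habitat` returns a [habitat_map()].
#' @export
write_habitat <- function(map, path) {
  write_ascii_grid(map$values, map$grid, path,
                   mask = matrix(FALSE, map$grid$rows, map$grid$cols),
                   nodata = -9999)
  jsonlite::write_json(map$classes, paste0(path, ".classes.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_habitat
#' @export
read_habitat <- function(path) {
  g <- read_ascii_grid(path)
  classes <- habitat_classes()
  sidecar <- paste0(path, ".classes.json")
  if (file.exists(sidecar))
    classes <- as.data.frame(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  habitat_map(g$values, g$grid, classes = classes)
}

#' Ground-truth and depth point tables
#'
#' Habitat points: columns `x`, `y`, `class` (integer code). Depth points:
#' columns `x`, `y`, `depth_m`.
#' @param points data.frame.
#' @param path CSV path.
#' @return `path` invisibly; readers return a data.frame.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_habitat_points <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "class")
  if (!all(need %in% names(df))) stop("habitat points CSV needs columns x, y, class")
  df$class <- as.integer(df$class)
  df
}

#' @rdname write_points_csv
#' @export
read_depth_points <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "depth_m") %in% names(df)))
    stop("depth points CSV needs columns x, y, depth_m")
  df
}

# ---------------------------------------------------------------------------
# Polygons: WKT POLYGON and GeoJSON Polygon, exterior ring only.

#' Parse a polygon from WKT or GeoJSON
#'
#' Accepts a WKT `POLYGON ((...))` string, a path to a file containing WKT,
#' or a path to a GeoJSON file with a `Polygon` geometry (bare geometry,
#' Feature or single-feature FeatureCollection). Only the exterior ring is
#' used; holes are ignored.
#'
#' @param x WKT string or file path.
#' @return two-column numeric matrix of ring vertices (closed ring not
#'   required).
#' @export
read_polygon <- function(x) {
  txt <- x
  if (length(x) == 1L && !grepl("POLYGON", x, ignore.case = TRUE) && file.exists(x))
    txt <- paste(readLines(x, warn = FALSE), collapse = "\n")
  if (grepl("^\\s*\\{", txt)) return(geojson_polygon(txt))
  parse_wkt_polygon(txt)
}

parse_wkt_polygon <- function(txt) {
  m <- regmatches(txt, regexpr("POLYGON\\s*\\(\\(.*?\\)", txt, ignore.case = TRUE))
  if (!length(m)) stop("not a WKT POLYGON: ", substr(txt, 1, 60))
  inner <- sub(".*\\(\\(", "", m)
  inner <- sub("\\).*", "", inner)
  pairs <- strsplit(trimws(strsplit(inner, ",")[[1]]), "[[:space:]]+")
  coords <- t(vapply(pairs, function(p) as.numeric(p[1:2]), numeric(2)))
  if (any(!is.finite(coords))) stop("malformed WKT coordinates")
  colnames(coords) <- c("x", "y")
  coords
}

geojson_polygon <- function(txt) {
  g <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (identical(g$type, "FeatureCollection")) g <- g$features$geometry
  if (!is.null(g$geometry)) g <- g$geometry
  ring <- g$coordinates
  if (is.list(ring)) ring <- ring[[1]]
  if (length(dim(ring)) == 3L) ring <- ring[1, , ]
  coords <- matrix(as.numeric(ring), ncol = 2)
  colnames(coords) <- c("x", "y")
  coords
}

# even-odd rule point-in-polygon; boundary points count as inside
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read / write a JSON configuration
#'
#' Configs round-trip losslessly through JSON; nested blocks (`optics`,
#' `rf`, `bathymetry`) are plain lists.
#' @param path JSON file path.
#' @param config a list.
#' @return `read_config` returns a list; `write_config` returns `path`.
#' @export
read_config <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
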