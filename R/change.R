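#' Per-class area in hectares
#'
#' `area = pixel_count * pixel_size^2 / 10^4`; masked (code 0) pixels are
#' excluded and reported separately.
#'
#' @param map a [habitat_map()].
#' @return named numeric vector of areas (ha) per class, with attribute
#'   `masked_ha`.
#' @export
class_area <- function(map) {
  px_ha <- map$grid$pixel_size^2 / 1e4
  counts <- vapply(map$classes$code, function(k) sum(map$values == k), integer(1))
  out <- counts * px_ha
  names(out) <- map$classes$label
  attr(out, "masked_ha") <- sum(map$values == 0L) * px_ha
  out
}

#' Signed percent change between two areas
#'
#' `100 * (end - start) / start`, with the earlier epoch as the baseline
#' denominator (the conventional choice; configurable only by swapping the
#' arguments deliberately).
#'
#' @param area_start baseline area (> 0).
#' @param area_end later area.
#' @return signed percentage.
#' @export
percent_change <- function(area_start, area_end) {
  if (any(area_start <= 0)) stop("zero or negative baseline area")
  100 * (area_end - area_start) / area_start
}

#' Linear trend of area over calendar years
#'
#' OLS regression of area (ha) on calendar year for each class; years may
#' be unevenly spaced (e.g. 2011, 2012, 2015, 2016) and enter as integers,
#' not epoch indices.
#'
#' @param series data.frame with columns `class`, `year`, `area_ha`.
#' @return data.frame with `class`, `slope_ha_yr`, `intercept_ha`,
#'   `r_squared`.
#' @export
area_trend <- function(series) {
  stopifnot(all(c("class", "year", "area_ha") %in% names(series)))
  res <- lapply(split(series, series$class), function(d) {
    if (length(unique(d$year)) < 2) stop("need >= 2 distinct years per class")
    fit <- stats::lm(area_ha ~ year, data = d)
    s <- suppressWarnings(summary(fit))  # constant series: perfect-fit warning
    data.frame(class = d$class[1],
               slope_ha_yr = unname(stats::coef(fit)[2]),
               intercept_ha = unname(stats::coef(fit)[1]),
               r_squared = s$r.squared)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-pixel gain / no-change / loss map for one class
#'
#' Compares two epochs for a single target class. Codes: 1 = gain
#' (absent -> present), 2 = no change, present in both, 3 = loss
#' (present -> absent), 4 = absent in both, 0 = masked in either epoch.
#' The codes partition all pixels.
#'
#' @param map_t0,map_t1 [habitat_map()]s on the same grid.
#' @param target_class class code (1-4) to track.
#' @return object of class `change_map`: integer code matrix plus counts
#'   and the implied area change.
#' @export
change_map <- function(map_t0, map_t1, target_class) {
  stop_if_grid_mismatch(map_t0$grid, map_t1$grid, "epoch maps")
  if (!target_class %in% map_t0$classes$code) stop("unknown target class code")
  masked <- map_t0$values == 0L | map_t1$values == 0L
  p0 <- map_t0$values == target_class
  p1 <- map_t1$values == target_class
  code <- matrix(4L, map_t0$grid$rows, map_t0$grid$cols)
  code[p1 & !p0] <- 1L
  code[p1 & p0] <- 2L
  code[!p1 & p0] <- 3L
  code[masked] <- 0L
  counts <- c(gain = sum(code == 1L), no_change_present = sum(code == 2L),
              loss = sum(code == 3L), absent_both = sum(code == 4L),
              masked = sum(code == 0L))
  structure(list(values = code, grid = map_t0$grid,
                 target_class = target_class,
                 class_label = map_t0$classes$label[
                   match(target_class, map_t0$classes$code)],
                 counts = counts,
                 legend = c(`0` = "masked", `1` = "gain", `2` = "no_change_present",
                            `3` = "loss", `4` = "absent_both")),
            class = "change_map")
}

#' @export
print.change_map <- function(x, ...) {
  cat(sprintf("<change_map> class %d (%s): gain %d, no-change %d, loss %d px\n",
              x$target_class, x$class_label,
              x$counts["gain"], x$counts["no_change_present"], x$counts["loss"]))
  invisible(x)
}

#' Cross-class transition matrix between two epochs
#'
#' Optional extra product: counts of pixels moving from class `i` (rows,
#' earlier epoch) to class `j` (columns, later epoch) over jointly
#' classified pixels.
#'
#' @param map_t0,map_t1 [habitat_map()]s on the same grid.
#' @return integer matrix of pixel counts.
#' @export
transition_matrix <- function(map_t0, map_t1) {
  stop_if_grid_mismatch(map_t0$grid, map_t1$grid, "epoch maps")
  ok <- map_t0$values != 0L & map_t1$values != 0L
  codes <- map_t0$classes$code
  m <- table(factor(map_t0$values[ok], levels = codes),
             factor(map_t1$values[ok], levels = codes))
  m <- unclass(as.matrix(m))
  dimnames(m) <- list(from = map_t0$classes$label, to = map_t1$classes$label)
  m
}
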