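#' Pipeline configuration
#'
#' Ties the stages together for a multi-epoch run. Each epoch supplies an
#' at-surface reflectance scene plus training and validation habitat
#' points; bathymetry is derived once from a designated reference epoch
#' (by default the last, i.e. the epoch closest to the in-situ campaign)
#' and shared across all epochs.
#'
#' @param epochs list; each element a list with `surface` (a
#'   [reflectance_scene()] or a scene stem path), `train_points`,
#'   `val_points` (data.frames or CSV paths).
#' @param years integer calendar years, one per epoch.
#' @param optics an [optical_constants()].
#' @param bathymetry list; `mode = "fit"` (default) with `calib_points`
#'   (data.frame or CSV) and optional `reference_epoch` (default last
#'   epoch), or `mode = "raster"` with `depth` (a [depth_raster()] or
#'   `.asc` path), or `mode = "coefficients"` with `coefficients`
#'   `c(a2, a1, a0)`.
#' @param mask_limit optically deep limit in metres, default 16.5.
#' @param rf an [rf_config()]; its seed is combined with `seed`.
#' @param target_classes class codes tracked in change maps, default
#'   `c(1, 2)` (the two seagrasses).
#' @param out_dir optional output directory for written products.
#' @param seed global seed; together with the epoch index it determines
#'   every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(epochs, years, optics = optical_constants(),
                            bathymetry = list(mode = "fit"),
                            mask_limit = 16.5, rf = rf_config(),
                            target_classes = c(1L, 2L),
                            out_dir = NULL, seed = 42L) {
  if (length(epochs) != length(years))
    stop("years must align 1:1 with epochs")
  if (length(years) > 1 && any(diff(order(years)) != 1))
    stop("years must be given in increasing order")
  structure(list(epochs = epochs, years = as.integer(years), optics = optics,
                 bathymetry = bathymetry, mask_limit = mask_limit, rf = rf,
                 target_classes = as.integer(target_classes),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_scene <- function(x) if (inherits(x, "reflectance_scene")) x else read_scene(x)
resolve_points <- function(x) if (is.data.frame(x)) x else read_habitat_points(x)
resolve_depth_points <- function(x) if (is.data.frame(x)) x else read_depth_points(x)

#' Run the full change-detection pipeline
#'
#' For every epoch: surface reflectance is masked at the optically deep
#' limit using the shared bathymetry, inverted to bottom reflectance,
#' classified with a random forest trained on that epoch's training
#' points, and validated against its validation points. Areas are computed
#' per class and year, trends fitted, and gain/no-change/loss maps built
#' for the target classes between the first and last epoch. A manifest
#' records parameters, seeds and products.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `bathymetry`, `habitat_maps`,
#'   `accuracy`, `area_series`, `trends`, `change_maps`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  epochs <- lapply(config$epochs, function(e) {
    list(surface = resolve_scene(e$surface),
         train_points = resolve_points(e$train_points),
         val_points = resolve_points(e$val_points))
  })
  g <- epochs[[1]]$surface$grid
  for (e in epochs) stop_if_grid_mismatch(g, e$surface$grid, "epoch scenes")

  depth <- shared_bathymetry(config, epochs)
  stop_if_grid_mismatch(g, depth$depth$grid, "scenes and bathymetry")

  maps <- list(); reports <- list()
  for (i in seq_along(epochs)) {
    e <- epochs[[i]]
    masked <- apply_deep_mask(e$surface, depth$depth, config$mask_limit)
    rb <- correct_water_column(masked, depth$depth, config$optics)
    feats <- extract_features(rb, e$train_points)
    warn_geographic_split(e$train_points, e$val_points)
    cfg <- config$rf
    cfg$rng_seed <- config$seed + i
    model <- train_classifier(feats, config = cfg)
    map <- classify_scene(model, rb)
    maps[[i]] <- map
    reports[[i]] <- accuracy_report(build_error_matrix(map, e$val_points))
  }
  names(maps) <- names(reports) <- as.character(config$years)

  areas <- do.call(rbind, lapply(seq_along(maps), function(i) {
    a <- class_area(maps[[i]])
    data.frame(class = names(a), year = config$years[i], area_ha = as.numeric(a))
  }))

  change <- NULL; trends <- NULL
  if (length(maps) >= 2) {
    trends <- area_trend(areas)
    change <- lapply(config$target_classes, function(k)
      change_map(maps[[1]], maps[[length(maps)]], k))
    names(change) <- habitat_classes()$label[match(config$target_classes,
                                                   habitat_classes()$code)]
  } else {
    warning("single epoch: change-detection stage skipped")
  }

  manifest <- list(package_version = as.character(utils::packageVersion("seagrassmapr")),
                   seed = config$seed,
                   years = config$years,
                   mask_limit_m = config$mask_limit,
                   optics = unclass(config$optics),
                   rf = unclass(config$rf),
                   bathymetry_model = if (!is.null(depth$model)) unclass(depth$model),
                   products = list(
                     habitat_maps = length(maps),
                     accuracy_reports = length(reports),
                     area_series_rows = nrow(areas),
                     change_maps = length(change)))

  result <- structure(list(bathymetry = depth$depth,
                           bathymetry_model = depth$model,
                           habitat_maps = maps, accuracy = reports,
                           area_series = areas, trends = trends,
                           change_maps = change, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_products(result, config)
  result
}

shared_bathymetry <- function(config, epochs) {
  b <- config$bathymetry
  mode <- if (is.null(b$mode)) "fit" else b$mode
  if (mode == "raster") {
    d <- if (inherits(b$depth, "depth_raster")) b$depth else read_depth(b$depth)
    return(list(depth = d, model = NULL))
  }
  ref <- if (!is.null(b$reference_epoch)) b$reference_epoch else length(epochs)
  rrs <- surface_to_rrs(epochs[[ref]]$surface, config$optics)
  if (mode == "coefficients") {
    model <- structure(list(coefficients = as.numeric(b$coefficients),
                            degree = length(b$coefficients) - 1L,
                            n_points = NA_integer_, r_squared = NA_real_,
                            residual_sd = NA_real_),
                       class = "bathymetry_model")
    ratio <- log_ratio(rrs)
    z <- smooth_depth(predict_depth(model, ratio, rrs$grid))
    return(list(depth = z, model = model))
  }
  if (mode != "fit") stop("unknown bathymetry mode: ", mode)
  if (is.null(b$calib_points)) stop("bathymetry mode 'fit' needs calib_points")
  est <- estimate_bathymetry(rrs, resolve_depth_points(b$calib_points))
  list(depth = est$depth, model = est$model)
}

warn_geographic_split <- function(train, val) {
  if (max(train$x) <= min(val$x) || max(val$x) <= min(train$x) ||
      max(train$y) <= min(val$y) || max(val$y) <= min(train$y))
    warning("training and validation points occupy disjoint halves of the ",
            "scene; accuracy estimates may carry a geographic bias",
            call. = FALSE)
  invisible(NULL)
}

write_pipeline_products <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (yr in names(result$habitat_maps)) {
    p <- file.path(config$out_dir, paste0("habitat_", yr, ".asc"))
    write_habitat(result$habitat_maps[[yr]], p)
    files <- c(files, p)
    rp <- file.path(config$out_dir, paste0("accuracy_", yr, ".json"))
    write_accuracy_report(result$accuracy[[yr]], rp)
    files <- c(files, rp)
  }
  ap <- file.path(config$out_dir, "area_series.csv")
  utils::write.csv(result$area_series, ap, row.names = FALSE)
  files <- c(files, ap)
  if (!is.null(result$change_maps)) {
    for (nm in names(result$change_maps)) {
      cm <- result$change_maps[[nm]]
      p <- file.path(config$out_dir,
                     sprintf("change_%s.asc", gsub("[. ]+", "_", nm)))
      write_ascii_grid(cm$values, cm$grid, p)
      files <- c(files, p)
    }
  }
  dp <- file.path(config$out_dir, "bathymetry.asc")
  write_depth(result$bathymetry, dp)
  files <- c(files, dp)
  manifest <- result$manifest
  manifest$files <- data.frame(path = basename(files),
                               md5 = unname(tools::md5sum(files)))
  write_config(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(files)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d epoch(s): %s\n",
              length(x$habitat_maps),
              paste(names(x$habitat_maps), collapse = ", ")))
  for (yr in names(x$accuracy))
    cat(sprintf("  %s overall accuracy %.1f%% (kappa %.3f)\n", yr,
                x$accuracy[[yr]]$overall_pct, x$accuracy[[yr]]$kappa))
  invisible(x)
}
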