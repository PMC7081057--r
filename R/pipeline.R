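#' Pool exposed runs and a no-laser control into one analysis table
#'
#' Runs the detection/tracking/fold-change stages on every acquisition of
#' a [simulate_experiment()]-shaped bundle (or any list with the same
#' shape built from real stacks), assigns doses to the exposed runs, and
#' rbinds everything with a logical `control` column and globally unique
#' cell ids.
#'
#' @param experiment list with `runs` (list of `list(frames = ...)`) and
#'   optional `control` (same shape).
#' @param map an [irradiance_map()] for the exposed runs.
#' @param ... passed to [analyze_frames()].
#' @return A pooled `"cell_tracks"` table ready for [dose_response()].
#' @export
analyze_experiment <- function(experiment, map, ...) {
  pieces <- list()
  for (k in seq_along(experiment$runs)) {
    tr <- analyze_frames(experiment$runs[[k]]$frames, map = map, ...)
    tr$control <- FALSE
    tr$run <- k
    pieces[[length(pieces) + 1L]] <- tr
  }
  if (!is.null(experiment$control)) {
    tr <- analyze_frames(experiment$control$frames, map = NULL, ...)
    tr$dose_x <- NA_real_
    tr$dose_y <- NA_real_
    tr$in_field <- FALSE
    tr$control <- TRUE
    tr$run <- 0L
    pieces[[length(pieces) + 1L]] <- tr
  }
  if (length(pieces) == 0L) stop("experiment contains no acquisitions")
  attrs <- attributes(pieces[[1L]])
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  out$cell_id <- seq_len(nrow(out))
  structure(out,
            baseline = attrs$baseline,
            timepoints = attrs$timepoints,
            wavelengths = c(x = map$fit_x$wavelength,
                            y = map$fit_y$wavelength),
            class = c("cell_tracks", "data.frame"))
}

#' Assemble and validate a pipeline configuration
#'
#' A pipeline run is fully described by one configuration (plus its seed),
#' so every output is regenerable from the configuration alone. The
#' configuration can be given as a named list or a YAML file with the same
#' structure; unspecified entries take the documented defaults.
#'
#' Top-level entries:
#' \describe{
#'   \item{calibration}{either `x`/`y` sub-lists with `coefficients` (and
#'     `wavelength`), or with `profiles` (a beam-profile CSV path) fitted
#'     by AIC degree selection over `degrees`.}
#'   \item{images}{either `stack` (TIFF path) + `timepoints`, or
#'     `synthetic` with scene parameters, `n_runs` and `control`.}
#'   \item{detection}{`threshold` (`"auto"` or a number), `window`,
#'     `tolerance_px`, `measure`, `subtract_background`, `sigma`.}
#'   \item{bins}{`n` per axis, or explicit `edges_x`/`edges_y`.}
#'   \item{alpha, pixel_size, field_extent, seed, out_dir}{scalars.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return Validated configuration list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  config$alpha <- config$alpha %||% 0.05
  config$pixel_size <- config$pixel_size %||% 1.6
  config$field_extent <- config$field_extent %||% c(1200, 1200)
  config$seed <- as.integer(config$seed %||% 1L)
  config$detection <- utils::modifyList(
    list(threshold = "auto", window = 5L, tolerance_px = 2,
         measure = "raw", subtract_background = TRUE, sigma = 0.85),
    config$detection %||% list())
  config$bins <- config$bins %||% list(n = c(5L, 5L))
  if (is.null(config$calibration))
    stop("config must define a 'calibration' section")
  if (is.null(config$images))
    stop("config must define an 'images' section")
  class(config) <- c("pipeline_config", "list")
  config
}

.calibrate_axis <- function(axis_cfg, axis) {
  if (!is.null(axis_cfg$coefficients))
    return(as_beam_fit(as.numeric(axis_cfg$coefficients),
                       wavelength = axis_cfg$wavelength %||% NA_real_))
  if (!is.null(axis_cfg$profiles)) {
    prof <- if (is.character(axis_cfg$profiles))
      read_beam_profiles(axis_cfg$profiles) else axis_cfg$profiles
    return(fit_beam_profile(prof$position_um, prof$irradiance_mw_cm2,
                            degree = NULL,
                            candidates = axis_cfg$degrees %||% 0:6,
                            wavelength = axis_cfg$wavelength %||% NA_real_))
  }
  stop(sprintf("calibration '%s' needs 'coefficients' or 'profiles'", axis))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes calibrate (or load fits) -> smooth -> detect -> link -> fold
#' change -> dose map -> bin -> summarise -> test, writing the calibration
#' JSONs, per-cell CSV, grid CSV, comparison CSV, the colour-map PNG and a
#' machine-readable run log into `out_dir`. A failing stage aborts with
#' the stage name; partially written outputs are removed.
#'
#' @param config a [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @return Invisibly, a list with the calibration fits, the irradiance
#'   map, the pooled `tracks`, the [dose_response()] fit and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, obj, file) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  stage <- "calibrate"
  result <- tryCatch({
    fit_x <- .calibrate_axis(config$calibration$x, "x")
    fit_y <- .calibrate_axis(config$calibration$y, "y")
    map <- irradiance_map(fit_x, fit_y, pixel_size = config$pixel_size,
                          field_extent = config$field_extent)
    emit(write_calibration, fit_x, "calibration_x.json")
    emit(write_calibration, fit_y, "calibration_y.json")

    stage <- "images"
    img <- config$images
    if (!is.null(img$synthetic)) {
      syn <- img$synthetic
      scene_args <- syn[setdiff(names(syn), c("n_runs", "control"))]
      experiment <- do.call(simulate_experiment, c(
        list(map = map, n_runs = syn$n_runs %||% 1L,
             control = syn$control %||% TRUE, seed = config$seed),
        scene_args))
    } else {
      frames <- read_stack(img$stack, img$timepoints)
      experiment <- list(runs = list(list(frames = frames)), control = NULL)
    }
    tps <- if (!is.null(img$synthetic))
      names(experiment$runs[[1]]$frames) else img$timepoints
    if (length(tps) < 2L)
      stop("nothing to compare: the series has no post-baseline frames")

    stage <- "detect/track"
    det <- config$detection
    tracks <- analyze_experiment(experiment, map,
                                 threshold = det$threshold,
                                 window = det$window,
                                 tolerance_px = det$tolerance_px,
                                 measure = det$measure,
                                 subtract_background = det$subtract_background,
                                 sigma = det$sigma)
    emit(write_cells_csv, tracks, "cells.csv")

    stage <- "dose-response"
    scheme <- if (!is.null(config$bins$edges_x))
      dose_bin_scheme(config$bins$edges_x, config$bins$edges_y) else NULL
    dr <- dose_response(tracks, scheme = scheme, map = map,
                        alpha = config$alpha,
                        n_bins = rep(as.integer(config$bins$n %||% 5L),
                                     length.out = 2L))
    emit(write_grid_csv, dr, "grid.csv")
    emit(write_comparisons_csv, dr, "comparisons.csv")

    stage <- "report"
    png_path <- file.path(out_dir, "colormap.png")
    grDevices::png(png_path, width = 480 * max(1, length(dr$timepoints) - 1),
                   height = 480)
    plot(dr)
    grDevices::dev.off()
    written <- c(written, png_path)
    log <- list(
      package = "nirdose",
      version = as.character(utils::packageVersion("nirdose")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      seed = config$seed,
      config = unclass(config),
      outputs = basename(written)
    )
    log_path <- file.path(out_dir, "run_log.json")
    jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                         na = "null", force = TRUE)
    list(fit_x = fit_x, fit_y = fit_y, map = map, tracks = tracks,
         dose_response = dr, outputs = c(written, log_path))
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
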