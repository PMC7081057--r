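#' Read a time-lapse TIFF stack into labelled frames
#'
#' Reads a multi-page TIFF (one page per timepoint) preserving integer
#' pixel values, and labels the pages with the acquisition timepoints.
#'
#' @param path TIFF file path.
#' @param mapping character vector of timepoint labels, one per page, in
#'   page order (baseline first).
#' @return Named list of numeric matrices.
#' @export
read_stack <- function(path, mapping) {
  if (!file.exists(path)) stop(sprintf("stack '%s' does not exist", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(mapping))
    stop(sprintf("stack '%s' has %d page(s) but the mapping names %d timepoint(s)",
                 path, length(pages), length(mapping)))
  frames <- lapply(pages, function(p) {
    m <- as.matrix(p)
    storage.mode(m) <- "double"
    m
  })
  names(frames) <- mapping
  frames
}

#' Write labelled frames as a multi-page TIFF stack
#'
#' @param frames named list of numeric matrices with values in
#'   `[0, 2^bit_depth - 1]`.
#' @param path output TIFF path.
#' @param bit_depth bits per sample (8 or 16; default 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path, bit_depth = 16L) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a non-empty list of matrices")
  maxval <- 2^bit_depth - 1
  scaled <- lapply(frames, function(f) {
    if (any(f < 0 | f > maxval)) stop("frame values outside the bit depth range")
    f / maxval
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(bit_depth),
                  compression = "none")
  invisible(path)
}

#' Save / load a gradient calibration as JSON
#'
#' The JSON document stores the wavelength, selected degree, coefficients
#' at full double precision, RSS, sample count, AIC, the parameter
#' covariance (for confidence bands) and, when the fit came from AIC
#' selection, the candidate-degree AIC table. [read_calibration()]
#' restores a fully functional `"beam_fit"`.
#'
#' @param fit a `"beam_fit"`.
#' @param path JSON file path.
#' @return `path` invisibly ([write_calibration()]); a `"beam_fit"`
#'   ([read_calibration()]).
#' @export
write_calibration <- function(fit, path) {
  stopifnot(inherits(fit, "beam_fit"))
  doc <- list(
    wavelength_nm = fit$wavelength,
    degree = fit$degree,
    coefficients = as.numeric(fit$coefficients),
    rss = fit$rss,
    n_points = fit$n,
    df_residual = fit$df_residual,
    aic = fit$aic,
    scale = fit$scale,
    cov_scaled = fit$cov_scaled,
    aic_table = fit$aic_table
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.integer(doc$degree)
  coefs <- as.numeric(doc$coefficients)
  fit <- as_beam_fit(coefs, wavelength = doc$wavelength_nm %||% NA_real_)
  fit$rss <- doc$rss
  fit$n <- as.integer(doc$n_points)
  fit$df_residual <- as.integer(doc$df_residual)
  fit$aic <- doc$aic %||% NA_real_
  fit$scale <- doc$scale
  fit$coef_scaled <- coefs * fit$scale^(0:d)
  if (!is.null(doc$cov_scaled)) {
    cs <- matrix(as.numeric(unlist(doc$cov_scaled)), d + 1L, d + 1L,
                 byrow = TRUE)
    fit$cov_scaled <- cs
    scl <- fit$scale^(0:d)
    fit$covariance <- cs / tcrossprod(scl)
    fit$sigma2 <- if (fit$df_residual > 0L) fit$rss / fit$df_residual else NA_real_
  }
  if (!is.null(doc$aic_table)) fit$aic_table <- as.data.frame(doc$aic_table)
  fit
}

#' Read beam-profile line scans from CSV
#'
#' Expects the exchange header `replicate,position_um,irradiance_mw_cm2`.
#'
#' @param path CSV file path.
#' @return Data frame with those three columns.
#' @export
read_beam_profiles <- function(path) {
  d <- utils::read.csv(path)
  need <- c("replicate", "position_um", "irradiance_mw_cm2")
  if (!all(need %in% names(d)))
    stop(sprintf("beam-profile CSV must have columns %s",
                 paste(need, collapse = ", ")))
  d
}

#' Write the per-cell results table
#'
#' One row per tracked cell: baseline pixel position, assigned dose pair
#' (columns named by the calibrated wavelengths when known), per-timepoint
#' intensities and fold changes.
#'
#' @param tracks a `"cell_tracks"` table.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(tracks, path) {
  out <- as.data.frame(tracks)
  wl <- attr(tracks, "wavelengths")
  if (!is.null(wl) && !anyNA(wl)) {
    names(out)[names(out) == "dose_x"] <- sprintf("dose_%s_mw_cm2", wl["x"])
    names(out)[names(out) == "dose_y"] <- sprintf("dose_%s_mw_cm2", wl["y"])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the dose-response grid and comparison tables
#'
#' `write_grid_csv()` writes one row per dose group and timepoint with the
#' bin bounds, member count, mean fold change and SEM;
#' `write_comparisons_csv()` writes the control-vs-group Tukey results.
#'
#' @param dr a [dose_response()] fit.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(dr, path) {
  out <- as.data.frame(dr)
  wl <- dr$wavelengths
  if (!is.null(wl) && !anyNA(wl)) {
    names(out) <- sub("^bin_x_", sprintf("bin_%s_", wl["x"]), names(out))
    names(out) <- sub("^bin_y_", sprintf("bin_%s_", wl["y"]), names(out))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
write_comparisons_csv <- function(dr, path) {
  rows <- lapply(names(dr$comparisons), function(lab) {
    vc <- dr$comparisons[[lab]]$vs_control
    if (is.null(vc) || nrow(vc) == 0L) return(NULL)
    grp <- ifelse(vc$group_i == "control", vc$group_j, vc$group_i)
    # orient differences as group minus control
    md <- ifelse(vc$group_i == "control", -vc$mean_diff, vc$mean_diff)
    data.frame(timepoint = lab, group = grp, control = "control",
               mean_diff = md, q = vc$q, adj_p = vc$adj_p,
               significant = vc$significant)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(timepoint = character(0), group = character(0),
                      control = character(0), mean_diff = numeric(0),
                      q = numeric(0), adj_p = numeric(0),
                      significant = logical(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
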