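#' Link per-frame detections into stable cell tracks
#'
#' Cells are followed across timepoints by positional stability: every
#' baseline (pre-illumination) detection is matched to at most one
#' detection in each later frame by mutually exclusive nearest-neighbour
#' assignment (greedy on ascending Euclidean distance) within
#' `tolerance_px`. Baseline cells that miss a match in any analysed
#' timepoint are dropped, so retained tracks are cells stably located at
#' the same position over the whole series.
#'
#' @param detections named list of detection data frames (from
#'   [detect_cells()]), one per timepoint; names are the timepoint labels
#'   and must be unique.
#' @param baseline label of the pre-illumination frame (default: first).
#' @param tolerance_px maximum displacement (pixels) allowed between the
#'   baseline position and any later position. Default 2.
#' @param measure which intensity to carry into the track table:
#'   `"raw"` (unfiltered frame, the default) or `"smoothed"`.
#' @return A data frame of class `"cell_tracks"`: one row per retained
#'   cell with `cell_id`, baseline `col`/`row`, and per-timepoint
#'   `col_<t>`, `row_<t>`, `intensity_<t>` columns. Attributes `baseline`
#'   and `timepoints` record the series.
#' @export
track_cells <- function(detections, baseline = names(detections)[1],
                        tolerance_px = 2, measure = c("raw", "smoothed")) {
  measure <- match.arg(measure)
  if (!is.list(detections) || is.null(names(detections)) ||
      any(names(detections) == ""))
    stop("'detections' must be a named list of per-timepoint detection tables")
  if (anyDuplicated(names(detections)))
    stop("duplicate timepoint labels in 'detections'")
  if (!baseline %in% names(detections))
    stop(sprintf("baseline timepoint '%s' not present", baseline))
  if (!is.numeric(tolerance_px) || tolerance_px < 0)
    stop("'tolerance_px' must be >= 0")
  icol <- paste0("intensity_", measure)
  labels <- names(detections)
  base <- detections[[baseline]]
  nb <- nrow(base)
  others <- setdiff(labels, baseline)
  match_idx <- matrix(NA_integer_, nrow = nb, ncol = length(others),
                      dimnames = list(NULL, others))
  for (lab in others) {
    det <- detections[[lab]]
    if (nb == 0L || nrow(det) == 0L) next
    dx <- outer(base$col, det$col, `-`)
    dy <- outer(base$row, det$row, `-`)
    d <- sqrt(dx^2 + dy^2)
    ok <- which(d <= tolerance_px, arr.ind = TRUE)
    if (nrow(ok) == 0L) next
    ok <- ok[order(d[ok]), , drop = FALSE]
    used_b <- logical(nb); used_f <- logical(nrow(det))
    for (i in seq_len(nrow(ok))) {
      b <- ok[i, 1L]; f <- ok[i, 2L]
      if (!used_b[b] && !used_f[f]) {
        used_b[b] <- TRUE; used_f[f] <- TRUE
        match_idx[b, lab] <- f
      }
    }
  }
  keep <- if (length(others)) !apply(is.na(match_idx), 1L, any) else rep(TRUE, nb)
  kept <- which(keep)
  out <- data.frame(cell_id = seq_along(kept),
                    col = base$col[kept], row = base$row[kept])
  for (lab in labels) {
    if (lab == baseline) {
      src <- base[kept, , drop = FALSE]
    } else {
      src <- detections[[lab]][match_idx[kept, lab], , drop = FALSE]
    }
    out[[paste0("col_", lab)]] <- src$col
    out[[paste0("row_", lab)]] <- src$row
    out[[paste0("intensity_", lab)]] <- src[[icol]]
  }
  structure(out, baseline = baseline, timepoints = labels,
            class = c("cell_tracks", "data.frame"))
}

#' Per-cell fold changes against the pre-illumination baseline
#'
#' `fold_<t> = intensity_<t> / intensity_<baseline>`; the baseline fold is
#' exactly 1. Cells whose baseline intensity is not strictly positive
#' cannot be normalised and are excluded with a warning; the dropped rows
#' are kept in the `"excluded"` attribute with the reason.
#'
#' @param tracks a `"cell_tracks"` table from [track_cells()].
#' @param background optional named numeric vector of per-timepoint
#'   background levels subtracted from the intensities before the ratio is
#'   formed (names matching the timepoint labels). Use this to remove the
#'   camera background so fold changes reflect the cell signal itself.
#' @return `tracks` with `fold_<t>` columns appended.
#' @export
compute_fold_changes <- function(tracks, background = NULL) {
  labels <- attr(tracks, "timepoints")
  baseline <- attr(tracks, "baseline")
  if (is.null(labels) || is.null(baseline))
    stop("'tracks' must come from track_cells()")
  intens <- lapply(labels, function(lab) tracks[[paste0("intensity_", lab)]])
  names(intens) <- labels
  if (!is.null(background)) {
    if (is.null(names(background)) || !all(labels %in% names(background)))
      stop("'background' must be named by timepoint label")
    for (lab in labels) intens[[lab]] <- intens[[lab]] - background[[lab]]
  }
  base <- intens[[baseline]]
  bad <- !(base > 0) | !is.finite(base)
  if (any(bad)) {
    warning(sprintf(
      "%d cell(s) excluded: non-positive baseline intensity cannot be normalised",
      sum(bad)))
  }
  excluded <- tracks[bad, , drop = FALSE]
  tracks <- tracks[!bad, , drop = FALSE]
  for (lab in labels)
    tracks[[paste0("fold_", lab)]] <-
      if (lab == baseline) rep(1, nrow(tracks))
      else intens[[lab]][!bad] / base[!bad]
  attr(tracks, "excluded") <- excluded
  attr(tracks, "baseline") <- baseline
  attr(tracks, "timepoints") <- labels
  class(tracks) <- c("cell_tracks", "data.frame")
  tracks
}

#' Attach dual-wavelength doses to tracked cells
#'
#' Doses are assigned from the baseline (pre-laser) position of each track
#' through the calibrated [irradiance_map()]. Cells outside the calibrated
#' field are flagged `in_field = FALSE` and treated as unexposed
#' downstream.
#'
#' @param tracks a `"cell_tracks"` table.
#' @param map an [irradiance_map()].
#' @return `tracks` with `dose_x`, `dose_y`, `in_field` columns appended
#'   and the map wavelengths stored in the `"wavelengths"` attribute.
#' @export
assign_doses <- function(tracks, map) {
  d <- dose_at(map, tracks$col, tracks$row)
  tracks$dose_x <- d$dose_x
  tracks$dose_y <- d$dose_y
  tracks$in_field <- d$in_field
  attr(tracks, "wavelengths") <- c(x = map$fit_x$wavelength,
                                   y = map$fit_y$wavelength)
  class(tracks) <- c("cell_tracks", "data.frame")
  tracks
}

#' Detect, track, normalise and dose-map a full time-lapse stack
#'
#' Convenience wrapper running the per-frame stages in order: 3x3 Gaussian
#' smoothing, local-maximum cell calling, positional-stability linking,
#' background-corrected fold changes, and dose assignment through the
#' calibration map. Intensities are measured on the unfiltered frames by
#' default while detection runs on the filtered frames.
#'
#' @param frames named list of numeric matrices, one per timepoint, in
#'   acquisition order; the first (or `baseline`) is the pre-illumination
#'   frame.
#' @param map an [irradiance_map()], or `NULL` to skip dose assignment
#'   (e.g. for a no-laser control acquisition).
#' @param threshold `"auto"` (median + 5 MAD of each smoothed frame) or a
#'   fixed numeric threshold.
#' @param window detection window side (odd, default 5).
#' @param baseline baseline timepoint label (default first frame).
#' @param tolerance_px tracking tolerance in pixels (default 2).
#' @param measure measure intensities on the `"raw"` (default) or
#'   `"smoothed"` frames.
#' @param subtract_background subtract each frame's median intensity
#'   before computing fold changes (default `TRUE`).
#' @param sigma smoothing sigma in pixels.
#' @return A `"cell_tracks"` table with fold changes and (if `map` is
#'   given) doses.
#' @export
analyze_frames <- function(frames, map = NULL, threshold = "auto",
                           window = 5L, baseline = names(frames)[1],
                           tolerance_px = 2, measure = c("raw", "smoothed"),
                           subtract_background = TRUE, sigma = 0.85) {
  measure <- match.arg(measure)
  if (!is.list(frames) || is.null(names(frames)))
    stop("'frames' must be a named list of matrices")
  dets <- lapply(names(frames), function(lab) {
    f <- frames[[lab]]
    sm <- gaussian_smooth(f, sigma = sigma)
    thr <- if (identical(threshold, "auto")) auto_threshold(sm)
           else as.numeric(threshold)
    detect_cells(sm, raw = f, threshold = thr, window = window,
                 frame_label = lab)
  })
  names(dets) <- names(frames)
  tracks <- track_cells(dets, baseline = baseline,
                        tolerance_px = tolerance_px, measure = measure)
  bg <- NULL
  if (subtract_background) {
    bg <- vapply(frames, function(f) stats::median(f), numeric(1))
    names(bg) <- names(frames)
  }
  tracks <- compute_fold_changes(tracks, background = bg)
  if (!is.null(map)) tracks <- assign_doses(tracks, map)
  tracks
}
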