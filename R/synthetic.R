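#' Simulate replicated beam-profile line scans
#'
#' Draws noisy line scans of a known gradient polynomial, emulating
#' replicated beam-profiler measurements along one gradient axis. Noise is
#' multiplicative Gaussian: `irradiance = truth(position) * (1 + eps)`,
#' `eps ~ N(0, noise_sd_frac)`, independent across positions and
#' replicates. Fully reproducible for a given seed.
#'
#' @param truth a `"beam_fit"` or coefficient vector defining the true
#'   gradient (e.g. [gradient_coefficients()]).
#' @param positions scan positions in micron; default a 20-micron grid
#'   over the 1.2 mm field.
#' @param n_replicates number of repeated scans (default 5).
#' @param noise_sd_frac relative noise sd (default 0.02, i.e. 2% of the
#'   local signal).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return Data frame with columns `replicate`, `position_um`,
#'   `irradiance_mw_cm2`.
#' @export
simulate_beam_profiles <- function(truth, positions = seq(0, 1200, by = 20),
                                   n_replicates = 5L, noise_sd_frac = 0.02,
                                   seed = NULL) {
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1")
  if (noise_sd_frac < 0) stop("'noise_sd_frac' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  mu <- evaluate_irradiance(truth, positions)
  np <- length(positions)
  eps <- if (noise_sd_frac > 0) stats::rnorm(np * n_replicates, 0, noise_sd_frac)
         else numeric(np * n_replicates)
  data.frame(
    replicate = rep(seq_len(n_replicates), each = np),
    position_um = rep(positions, times = n_replicates),
    irradiance_mw_cm2 = rep(mu, times = n_replicates) * (1 + eps)
  )
}

#' Dose-dependent fold-change response model
#'
#' The generator's ground-truth biology: cells whose dose pair falls in
#' the suppression window respond with the `fold_inside` trajectory,
#' everyone else (including unexposed controls) with `fold_outside`; a
#' between-cell Gaussian spread of sd `cell_sd` is added around the
#' programmed mean at each post-baseline timepoint. Defaults encode
#' transient suppression (fold 0.85 at the middle timepoint inside the
#' 250-400 x 55-65 mW/cm^2 window, recovery to 1.0 by the last).
#'
#' @param window_x,window_y dose interval (mW/cm^2) of the suppression
#'   window on the x (1064 nm) and y (1270 nm) gradient axes.
#' @param fold_inside,fold_outside programmed mean fold change per
#'   timepoint (first entry is the baseline and must be 1).
#' @param cell_sd between-cell sd of the realised fold changes.
#' @return Object of class `"response_model"`.
#' @export
response_model <- function(window_x = c(250, 400), window_y = c(55, 65),
                           fold_inside = c(1, 0.85, 1),
                           fold_outside = c(1, 1, 1),
                           cell_sd = 0.10) {
  if (length(fold_inside) != length(fold_outside))
    stop("'fold_inside' and 'fold_outside' must have the same length")
  if (any(fold_inside <= 0) || any(fold_outside <= 0))
    stop("programmed fold changes must be positive")
  if (fold_inside[1] != 1 || fold_outside[1] != 1)
    stop("the baseline (first) fold must be 1")
  structure(list(window_x = as.numeric(window_x),
                 window_y = as.numeric(window_y),
                 fold_inside = as.numeric(fold_inside),
                 fold_outside = as.numeric(fold_outside),
                 cell_sd = cell_sd),
            class = "response_model")
}

#' Define a synthetic fluorescence time-lapse scene
#'
#' Parameters of a simulated acquisition: point-like cells rendered with
#' an isotropic Gaussian PSF on a noisy camera background, imaged at the
#' acquisition timepoints with uniform photobleaching per frame. The
#' default scene is the 1.2 x 1.2 mm gradient field at 1.6 micron/px
#' (750 x 750 px), cell density about 1 per 40 x 40 px, PSF sigma 2 px,
#' 16-bit output.
#'
#' @param n_cells number of cells; default derived from a density of
#'   1/1600 px^-2.
#' @param frame_px frame size `(rows, cols)` in pixels.
#' @param pixel_size micron per pixel.
#' @param psf_sigma PSF sigma in pixels.
#' @param background camera background level (counts).
#' @param read_noise_frac Gaussian read-noise sd as a fraction of the
#'   background (default 0.02).
#' @param poisson add Poisson shot noise (default `FALSE`, keeping
#'   noise-free renders exact when `read_noise_frac = 0`).
#' @param bleach photobleaching fraction per acquisition (default 0.02:
#'   every frame after the first is attenuated by `(1 - bleach)^k`).
#' @param amplitude_range baseline peak amplitudes, drawn uniformly.
#' @param min_separation minimum pairwise distance between cell centres
#'   (px); at least the detection window so neighbouring PSFs cannot
#'   shadow each other's maxima. Set `0` to disable.
#' @param jitter_sd per-frame positional jitter sd (px) applied after the
#'   baseline frame.
#' @param timepoints acquisition labels, baseline first.
#' @param response a [response_model()] with one fold entry per timepoint.
#' @param bit_depth camera bit depth; frames are clipped and rounded to
#'   integers in `[0, 2^bit_depth - 1]`.
#' @param laser_on `FALSE` renders a no-laser control acquisition: cells
#'   carry no dose and respond with the outside-window trajectory.
#' @param seed integer seed making the scene fully reproducible.
#' @return Object of class `"synthetic_scene"`.
#' @export
synthetic_scene <- function(n_cells = NULL, frame_px = c(750L, 750L),
                            pixel_size = 1.6, psf_sigma = 2,
                            background = 100, read_noise_frac = 0.02,
                            poisson = FALSE, bleach = 0.02,
                            amplitude_range = c(600, 1200),
                            min_separation = 8, jitter_sd = 0.3,
                            timepoints = c("pre", "1min", "5min"),
                            response = response_model(),
                            bit_depth = 16L, laser_on = TRUE, seed = 1L) {
  frame_px <- rep(as.integer(frame_px), length.out = 2L)
  if (any(frame_px < 8L)) stop("'frame_px' too small")
  if (is.null(n_cells)) n_cells <- round(prod(frame_px) / 1600)
  if (n_cells < 0L) stop("'n_cells' must be >= 0")
  if (length(response$fold_inside) != length(timepoints))
    stop("response model must define one fold per timepoint")
  if (anyDuplicated(timepoints)) stop("timepoint labels must be unique")
  structure(list(
    n_cells = as.integer(n_cells), frame_px = frame_px,
    pixel_size = pixel_size, psf_sigma = psf_sigma,
    background = background, read_noise_frac = read_noise_frac,
    poisson = poisson, bleach = bleach,
    amplitude_range = as.numeric(amplitude_range),
    min_separation = min_separation, jitter_sd = jitter_sd,
    timepoints = timepoints, response = response,
    bit_depth = as.integer(bit_depth), laser_on = isTRUE(laser_on),
    seed = as.integer(seed)
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "Synthetic scene: %d cells on %d x %d px (%.3g um/px), %s\n",
    x$n_cells, x$frame_px[1], x$frame_px[2], x$pixel_size,
    if (x$laser_on) "laser on" else "no-laser control"))
  cat(sprintf("  timepoints: %s; PSF sigma %.3g px; background %g; seed %d\n",
              paste(x$timepoints, collapse = ", "), x$psf_sigma,
              x$background, x$seed))
  invisible(x)
}

#' Draw the ground-truth cell field of a synthetic scene
#'
#' Places cells uniformly at random with a minimum pairwise separation
#' (dart throwing), assigns each its dose pair through the irradiance map
#' (or flags it control when the laser is off / the cell is outside the
#' field), and draws the realised per-cell fold changes from the response
#' model. The expected rendered intensity ratio per timepoint
#' (`ratio_<t>` = realised fold x bleaching factor) is recorded so the
#' pipeline's measurements can be compared with what was actually
#' rendered.
#'
#' @param scene a [synthetic_scene()].
#' @param map an [irradiance_map()], or `NULL` for a no-laser control.
#' @return Ground-truth data frame: `cell_id`, sub-pixel `x_px`/`y_px`
#'   (0-based, x = column axis), `amplitude`, `dose_x`, `dose_y`,
#'   `control`, `in_window`, and `fold_<t>` / `ratio_<t>` per timepoint.
#' @export
simulate_cell_field <- function(scene, map = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  set.seed(scene$seed)
  n <- scene$n_cells
  nr <- scene$frame_px[1]; ncg <- scene$frame_px[2]
  margin <- ceiling(3 * scene$psf_sigma)
  if (n > 0L) {
    xs <- numeric(n); ys <- numeric(n)
    placed <- 0L; attempts <- 0L; max_attempts <- 400L * n
    while (placed < n) {
      if (attempts >= max_attempts)
        stop(sprintf(
          "infeasible packing: placed %d of %d cells at min separation %.1f px",
          placed, n, scene$min_separation))
      attempts <- attempts + 1L
      cx <- stats::runif(1, margin, ncg - 1 - margin)
      cy <- stats::runif(1, margin, nr - 1 - margin)
      if (placed > 0L && scene$min_separation > 0) {
        d2 <- (xs[seq_len(placed)] - cx)^2 + (ys[seq_len(placed)] - cy)^2
        if (min(d2) < scene$min_separation^2) next
      }
      placed <- placed + 1L
      xs[placed] <- cx; ys[placed] <- cy
    }
  } else {
    xs <- ys <- numeric(0)
  }
  amp <- stats::runif(n, scene$amplitude_range[1], scene$amplitude_range[2])
  laser <- scene$laser_on && !is.null(map)
  if (laser) {
    d <- dose_at(map, xs, ys)
    control <- !d$in_field
    dose_x <- ifelse(control, NA_real_, d$dose_x)
    dose_y <- ifelse(control, NA_real_, d$dose_y)
  } else {
    control <- rep(TRUE, n)
    dose_x <- dose_y <- rep(NA_real_, n)
  }
  rm_ <- scene$response
  in_window <- !control &
    dose_x >= rm_$window_x[1] & dose_x <= rm_$window_x[2] &
    dose_y >= rm_$window_y[1] & dose_y <= rm_$window_y[2]
  in_window[is.na(in_window)] <- FALSE
  truth <- data.frame(cell_id = seq_len(n), x_px = xs, y_px = ys,
                      amplitude = amp, dose_x = dose_x, dose_y = dose_y,
                      control = control, in_window = in_window)
  tps <- scene$timepoints
  for (k in seq_along(tps)) {
    mu <- ifelse(in_window, rm_$fold_inside[k], rm_$fold_outside[k])
    fold <- if (k == 1L) rep(1, n)
            else pmax(stats::rnorm(n, mu, rm_$cell_sd), 0.05)
    truth[[paste0("fold_", tps[k])]] <- fold
    truth[[paste0("ratio_", tps[k])]] <- fold * (1 - scene$bleach)^(k - 1L)
  }
  truth
}

#' Render the time-lapse frames of a synthetic scene
#'
#' Each frame is `background + sum(amplitude * ratio(t) * PSF) + noise`,
#' clipped and rounded to the camera bit depth. Cell positions are
#' jittered per post-baseline frame by `jitter_sd`. Deterministic in
#' `(scene, map)`: the same seed reproduces identical frames and ground
#' truth.
#'
#' @param scene a [synthetic_scene()].
#' @param map optional [irradiance_map()] for dose assignment.
#' @param truth optional precomputed [simulate_cell_field()] table; when
#'   omitted it is generated from the scene seed.
#' @return List with `frames` (named list of integer-valued matrices, one
#'   per timepoint) and `truth` (the ground-truth table).
#' @export
render_frames <- function(scene, map = NULL, truth = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (is.null(truth)) truth <- simulate_cell_field(scene, map)
  nr <- scene$frame_px[1]; ncg <- scene$frame_px[2]
  tps <- scene$timepoints
  maxval <- 2^scene$bit_depth - 1
  R <- ceiling(4 * scene$psf_sigma)
  s2 <- 2 * scene$psf_sigma^2
  frames <- vector("list", length(tps))
  names(frames) <- tps
  for (k in seq_along(tps)) {
    set.seed(scene$seed + 7919L * k)
    img <- matrix(scene$background, nr, ncg)
    n <- nrow(truth)
    jx <- if (k == 1L || scene$jitter_sd <= 0) numeric(n)
          else stats::rnorm(n, 0, scene$jitter_sd)
    jy <- if (k == 1L || scene$jitter_sd <= 0) numeric(n)
          else stats::rnorm(n, 0, scene$jitter_sd)
    ratio <- truth[[paste0("ratio_", tps[k])]]
    for (i in seq_len(n)) {
      cx <- truth$x_px[i] + jx[i]   # 0-based column position
      cy <- truth$y_px[i] + jy[i]
      cols <- max(0L, floor(cx - R)):min(ncg - 1L, ceiling(cx + R))
      rows <- max(0L, floor(cy - R)):min(nr - 1L, ceiling(cy + R))
      psf <- exp(-(outer((rows - cy)^2, (cols - cx)^2, `+`)) / s2)
      img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] +
        truth$amplitude[i] * ratio[i] * psf
    }
    if (scene$poisson)
      img <- matrix(stats::rpois(length(img), img), nr, ncg)
    if (scene$read_noise_frac > 0)
      img <- img + stats::rnorm(length(img), 0,
                                scene$read_noise_frac * scene$background)
    frames[[k]] <- matrix(round(pmin(pmax(img, 0), maxval)), nr, ncg)
  }
  list(frames = frames, truth = truth)
}

#' Simulate a complete dose-response experiment
#'
#' Renders `n_runs` independent laser-exposed acquisitions plus (by
#' default) one no-laser control acquisition, all sharing the scene
#' parameters but with run-specific seeds derived from `seed`. This is
#' the synthetic analogue of pooling replicate imaging runs and a control
#' group for the grid analysis.
#'
#' @param map an [irradiance_map()].
#' @param n_runs number of exposed acquisitions (default 2).
#' @param control include a no-laser control acquisition (default `TRUE`).
#' @param seed master seed; run k uses `seed + k`, the control
#'   `seed + n_runs + 1`.
#' @param ... scene parameters passed to [synthetic_scene()].
#' @return List with `runs` (list of [render_frames()] results) and
#'   `control` (one such result or `NULL`).
#' @export
simulate_experiment <- function(map, n_runs = 2L, control = TRUE,
                                seed = 42L, ...) {
  runs <- lapply(seq_len(n_runs), function(k) {
    sc <- synthetic_scene(..., laser_on = TRUE, seed = seed + k)
    render_frames(sc, map = map)
  })
  ctrl <- NULL
  if (control) {
    sc <- synthetic_scene(..., laser_on = FALSE, seed = seed + n_runs + 1L)
    ctrl <- render_frames(sc, map = NULL)
  }
  list(runs = runs, control = ctrl)
}
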