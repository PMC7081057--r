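#' Dose binning scheme for the irradiance-combination grid
#'
#' Ascending bin edges per gradient axis defining an `n_x x n_y` grid of
#' dose groups. Cells are assigned to half-open rectangles
#' `[e_i, e_{i+1}) x [f_j, f_{j+1})`, with the topmost edge closed so the
#' maximum attained dose is kept. The default used throughout is 5
#' equal-width bins per axis (25 groups) spanning the doses actually
#' mapped across the field.
#'
#' @param edges_x,edges_y strictly ascending numeric edges (mW/cm^2), at
#'   least 2 per axis.
#' @return Object of class `"dose_bin_scheme"`.
#' @export
dose_bin_scheme <- function(edges_x, edges_y) {
  for (e in list(edges_x, edges_y)) {
    if (length(e) < 2L || any(!is.finite(e)) || any(diff(e) <= 0))
      stop("bin edges must be >= 2 finite strictly ascending values")
  }
  structure(list(edges_x = as.numeric(edges_x),
                 edges_y = as.numeric(edges_y)),
            class = "dose_bin_scheme")
}

#' @rdname dose_bin_scheme
#' @param map an [irradiance_map()] whose attained dose ranges define the
#'   bin spans.
#' @param n number of bins per axis; scalar or length-2 `(n_x, n_y)`.
#' @export
dose_bin_scheme_from_map <- function(map, n = 5L) {
  n <- rep(as.integer(n), length.out = 2L)
  if (any(n < 1L)) stop("'n' must be >= 1 bins per axis")
  r <- dose_range(map)
  dose_bin_scheme(seq(r$range_x[1], r$range_x[2], length.out = n[1] + 1L),
                  seq(r$range_y[1], r$range_y[2], length.out = n[2] + 1L))
}

# Half-open bin index (topmost edge closed); NA when out of range.
.bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

#' Fit the dose-response grid and group comparisons
#'
#' The central analysis object: bins tracked cells into irradiance
#' combination groups, summarises each group's fold change (mean, SEM, n)
#' per timepoint, and tests group differences against the no-laser control
#' with one-way ANOVA followed by Tukey's multiple comparison test.
#'
#' Cells flagged as control (a `control` column, or `in_field = FALSE`, or
#' missing doses) form the no-laser reference group; the remaining cells
#' are assigned to the half-open dose rectangles of `scheme`. Groups with
#' fewer than 2 cells are excluded from inference with a warning. For each
#' post-baseline timepoint the comparison table reports, for every dose
#' group, the mean difference to control, the studentized-range statistic
#' `q` (Tukey-Kramer standard error for unequal n), the adjusted p value
#' and the significance flag at `alpha`.
#'
#' @param tracks a `"cell_tracks"` table carrying `fold_<t>` columns and
#'   doses (see [analyze_frames()]); control cells may be rbind-ed in with
#'   a logical `control` column.
#' @param scheme a [dose_bin_scheme()]; if `NULL` one is derived from
#'   `map` when given, otherwise 5 equal-width bins per axis spanning the
#'   in-field dose range of `tracks`.
#' @param map optional [irradiance_map()] used to derive the default
#'   scheme from the full field.
#' @param alpha familywise significance level, default 0.05.
#' @param n_bins bins per axis for a derived scheme, default `c(5, 5)`.
#' @return Object of class `"dose_response"` with components `scheme`,
#'   `stats` (per-timepoint list of `mean`/`sem`/`n` matrices, rows = y
#'   bins, columns = x bins), `comparisons` (per-timepoint
#'   `"dose_comparison"` vs control, when control cells exist), `counts`
#'   (in-range / out-of-range / control), `assignments`, `alpha`.
#' @examples
#' \donttest{
#' m <- irradiance_map(as_beam_fit(gradient_coefficients("1064"), 1064),
#'                     as_beam_fit(gradient_coefficients("1270"), 1270))
#' sc <- synthetic_scene(n_cells = 300, seed = 7)
#' run <- render_frames(sc, map = m)
#' tr <- analyze_frames(run$frames, map = m)
#' dr <- dose_response(tr, map = m)
#' print(dr)
#' }
#' @export
dose_response <- function(tracks, scheme = NULL, map = NULL,
                          alpha = 0.05, n_bins = c(5L, 5L)) {
  if (!is.data.frame(tracks) || is.null(tracks$dose_x) && is.null(tracks$control))
    stop("'tracks' must carry doses (assign_doses) and/or a 'control' column")
  labels <- attr(tracks, "timepoints")
  fold_cols <- grep("^fold_", names(tracks), value = TRUE)
  if (length(fold_cols) == 0L) stop("'tracks' has no fold_<timepoint> columns")
  if (is.null(labels)) labels <- sub("^fold_", "", fold_cols)
  baseline <- attr(tracks, "baseline")
  if (is.null(baseline)) baseline <- labels[1]
  if (is.null(tracks$dose_x)) tracks$dose_x <- NA_real_
  if (is.null(tracks$dose_y)) tracks$dose_y <- NA_real_
  if (is.null(tracks$in_field)) tracks$in_field <- !is.na(tracks$dose_x)
  is_control <- if (!is.null(tracks$control)) as.logical(tracks$control)
                else rep(FALSE, nrow(tracks))
  is_control <- is_control | !tracks$in_field | is.na(tracks$dose_x) |
    is.na(tracks$dose_y)
  exposed <- tracks[!is_control, , drop = FALSE]
  if (is.null(scheme)) {
    scheme <- if (!is.null(map)) dose_bin_scheme_from_map(map, n = n_bins)
    else {
      if (nrow(exposed) == 0L) stop("no exposed cells to derive a bin scheme from")
      dose_bin_scheme(
        seq(min(exposed$dose_x), max(exposed$dose_x), length.out = n_bins[1] + 1L),
        seq(min(exposed$dose_y), max(exposed$dose_y), length.out = n_bins[2] + 1L))
    }
  }
  if (!inherits(scheme, "dose_bin_scheme")) stop("'scheme' must be a dose_bin_scheme")
  nx <- length(scheme$edges_x) - 1L
  ny <- length(scheme$edges_y) - 1L
  bx <- .bin_index(exposed$dose_x, scheme$edges_x)
  by <- .bin_index(exposed$dose_y, scheme$edges_y)
  in_range <- !is.na(bx) & !is.na(by)
  assignments <- data.frame(cell_id = exposed$cell_id,
                            bin_x = bx, bin_y = by)[in_range, , drop = FALSE]
  group_of <- (by - 1L) * nx + bx   # 1..nx*ny, row-major over (bin_y, bin_x)
  stats_by_tp <- list()
  for (lab in labels) {
    fold <- exposed[[paste0("fold_", lab)]][in_range]
    g <- group_of[in_range]
    nmat <- matrix(0L, ny, nx)
    mmat <- matrix(NA_real_, ny, nx)
    smat <- matrix(NA_real_, ny, nx)
    if (length(fold)) {
      cnt <- tapply(fold, g, length)
      mu <- tapply(fold, g, mean)
      sdv <- tapply(fold, g, stats::sd)
      idx <- as.integer(names(cnt))
      nmat[cbind((idx - 1L) %/% nx + 1L, (idx - 1L) %% nx + 1L)] <- as.integer(cnt)
      mmat[cbind((idx - 1L) %/% nx + 1L, (idx - 1L) %% nx + 1L)] <- mu
      sem <- ifelse(cnt >= 2L, sdv / sqrt(cnt), NA_real_)
      smat[cbind((idx - 1L) %/% nx + 1L, (idx - 1L) %% nx + 1L)] <- sem
    }
    stats_by_tp[[lab]] <- list(mean = mmat, sem = smat, n = nmat)
  }
  # comparisons vs the no-laser control, per post-baseline timepoint
  comparisons <- list()
  ctrl <- tracks[is_control, , drop = FALSE]
  for (lab in setdiff(labels, baseline)) {
    fold <- exposed[[paste0("fold_", lab)]][in_range]
    g <- group_of[in_range]
    groups <- split(fold, g)
    big <- vapply(groups, length, integer(1)) >= 2L
    if (any(!big))
      warning(sprintf("%d dose group(s) with n < 2 excluded from inference (%s)",
                      sum(!big), lab))
    groups <- groups[big]
    gx <- (as.integer(names(groups)) - 1L) %% nx + 1L
    gy <- (as.integer(names(groups)) - 1L) %/% nx + 1L
    glabels <- sprintf("bin[%d,%d]", gx, gy)
    cf <- ctrl[[paste0("fold_", lab)]]
    if (length(cf) >= 2L) {
      all_groups <- c(list(control = cf), stats::setNames(groups, glabels))
      cmp <- try(tukey_hsd(all_groups, alpha = alpha), silent = TRUE)
      if (!inherits(cmp, "try-error")) {
        tk <- cmp$tukey
        vs_ctrl <- tk[tk$group_i == "control" | tk$group_j == "control", ,
                      drop = FALSE]
        cmp$vs_control <- vs_ctrl
        comparisons[[lab]] <- cmp
      }
    }
  }
  structure(list(
    scheme = scheme,
    stats = stats_by_tp,
    comparisons = comparisons,
    assignments = assignments,
    counts = c(in_range = sum(in_range),
               out_of_range = sum(!in_range),
               control = nrow(ctrl)),
    alpha = alpha,
    baseline = baseline,
    timepoints = labels,
    wavelengths = attr(tracks, "wavelengths")
  ), class = "dose_response")
}

#' Per-group mean, SEM and count matrices for one timepoint
#'
#' @param object a `"dose_response"` fit.
#' @param timepoint timepoint label; default the first post-baseline one.
#' @return List of matrices `mean`, `sem`, `n` (rows = y-axis dose bins,
#'   columns = x-axis dose bins); empty groups are `NA`.
#' @export
summarize_grid <- function(object, timepoint = NULL) {
  stopifnot(inherits(object, "dose_response"))
  if (is.null(timepoint))
    timepoint <- setdiff(object$timepoints, object$baseline)[1]
  if (!timepoint %in% names(object$stats))
    stop(sprintf("unknown timepoint '%s'", timepoint))
  object$stats[[timepoint]]
}

#' One-way analysis of variance for dose groups
#'
#' Classical fixed-effects decomposition `F = MS_between / MS_within`,
#' fitted with [stats::aov()]; p value from the F distribution with
#' `(g - 1, N - g)` degrees of freedom.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 finite
#'   observations.
#' @return List with `F`, `df_between`, `df_within`, `p_value`,
#'   `ms_within`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("every group needs at least 2 observations")
  y <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(y))) stop("observations must be finite")
  if (stats::var(y) == 0)
    stop("degenerate data: all observations are identical")
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw <= 1e-12 * sum((y - mean(y))^2))
    stop("zero within-group variance: F statistic is not defined")
  g <- factor(rep.int(seq_along(groups), sizes))
  tab <- summary(stats::aov(y ~ g))[[1]]
  msw <- tab[2L, "Mean Sq"]
  list(F = tab[1L, "F value"],
       df_between = tab[1L, "Df"],
       df_within = tab[2L, "Df"],
       p_value = tab[1L, "Pr(>F)"],
       ms_within = msw)
}

#' Tukey's multiple comparison test (Tukey-Kramer for unequal n)
#'
#' All-pairs comparison after one-way ANOVA. For groups i and j,
#' `q = |mean_i - mean_j| / sqrt(MS_within / 2 * (1/n_i + 1/n_j))` and the
#' adjusted p value is the upper tail of the studentized-range
#' distribution with `(g, N - g)` parameters ([stats::ptukey()], which
#' integrates the standard double-integral representation numerically).
#'
#' @param groups named (or unnamed) list of >= 2 numeric vectors with
#'   >= 2 observations each.
#' @param alpha familywise significance level, default 0.05.
#' @return Object of class `"dose_comparison"`: the `anova` decomposition
#'   plus a `tukey` data frame with one row per pair (`group_i`,
#'   `group_j`, `mean_diff`, `q`, `adj_p`, `significant`).
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  av <- one_way_anova(groups)
  gname <- names(groups)
  if (is.null(gname)) gname <- paste0("group", seq_along(groups))
  k <- length(groups)
  mu <- vapply(groups, mean, numeric(1))
  n <- lengths(groups)
  pairs <- utils::combn(k, 2L)
  i <- pairs[1L, ]; j <- pairs[2L, ]
  diff <- mu[i] - mu[j]
  se_q <- sqrt(av$ms_within / 2 * (1 / n[i] + 1 / n[j]))
  q <- abs(diff) / se_q
  adj_p <- stats::ptukey(q, nmeans = k, df = av$df_within, lower.tail = FALSE)
  structure(list(
    anova = av,
    tukey = data.frame(group_i = gname[i], group_j = gname[j],
                       mean_diff = as.numeric(diff), q = as.numeric(q),
                       adj_p = as.numeric(adj_p),
                       significant = as.numeric(adj_p) < alpha),
    alpha = alpha
  ), class = "dose_comparison")
}

#' @export
print.dose_comparison <- function(x, digits = 4L, ...) {
  a <- x$anova
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              a$df_between, a$df_within, a$F, a$p_value))
  cat(sprintf("Tukey multiple comparisons (alpha = %g):\n", x$alpha))
  tk <- x$tukey
  tk$mean_diff <- signif(tk$mean_diff, digits)
  tk$q <- signif(tk$q, digits)
  tk$adj_p <- signif(tk$adj_p, digits)
  print(utils::head(tk[order(tk$adj_p), ], 10L), row.names = FALSE)
  if (nrow(tk) > 10L) cat(sprintf("... (%d pairs total)\n", nrow(tk)))
  invisible(x)
}

#' @export
print.dose_response <- function(x, ...) {
  nx <- length(x$scheme$edges_x) - 1L
  ny <- length(x$scheme$edges_y) - 1L
  occ <- sum(x$stats[[1]]$n > 0L)
  cat(sprintf("Dose-response grid: %d x %d = %d groups (%d occupied)\n",
              nx, ny, nx * ny, occ))
  cat(sprintf("Cells: %d in range, %d out of range, %d control\n",
              x$counts["in_range"], x$counts["out_of_range"],
              x$counts["control"]))
  for (lab in setdiff(x$timepoints, x$baseline)) {
    s <- x$stats[[lab]]
    cat(sprintf("  %s: grid means %.3f-%.3f\n", lab,
                min(s$mean, na.rm = TRUE), max(s$mean, na.rm = TRUE)))
    cmp <- x$comparisons[[lab]]
    if (!is.null(cmp)) {
      sig <- cmp$vs_control[cmp$vs_control$significant, , drop = FALSE]
      cat(sprintf("     %d group(s) differ from control at alpha = %g\n",
                  nrow(sig), x$alpha))
    }
  }
  invisible(x)
}

#' @export
summary.dose_response <- function(object, ...) {
  as.data.frame(object)
}

#' Export the dose-response grid as a long table
#'
#' One row per dose group per timepoint: bin bounds on both axes, member
#' count, mean fold change and SEM (the layout of the grid CSV).
#'
#' @param x a `"dose_response"` fit.
#' @param ... unused.
#' @export
as.data.frame.dose_response <- function(x, ...) {
  ex <- x$scheme$edges_x; ey <- x$scheme$edges_y
  nx <- length(ex) - 1L; ny <- length(ey) - 1L
  grid <- expand.grid(bin_x = seq_len(nx), bin_y = seq_len(ny))
  out <- do.call(rbind, lapply(x$timepoints, function(lab) {
    s <- x$stats[[lab]]
    data.frame(timepoint = lab,
               bin_x_lo = ex[grid$bin_x], bin_x_hi = ex[grid$bin_x + 1L],
               bin_y_lo = ey[grid$bin_y], bin_y_hi = ey[grid$bin_y + 1L],
               n = s$n[cbind(grid$bin_y, grid$bin_x)],
               mean_fold = s$mean[cbind(grid$bin_y, grid$bin_x)],
               sem = s$sem[cbind(grid$bin_y, grid$bin_x)])
  }))
  rownames(out) <- NULL
  out
}

#' Color map of the dose-response grid
#'
#' Draws the per-group mean fold change as a colour map over the two dose
#' axes, one panel per requested timepoint; values below 1 (suppression)
#' shade towards blue, above 1 towards red.
#'
#' @param x a `"dose_response"` fit.
#' @param timepoint label(s) to draw; default all post-baseline ones.
#' @param ... passed to [graphics::image()].
#' @export
plot.dose_response <- function(x, timepoint = NULL, ...) {
  if (is.null(timepoint))
    timepoint <- setdiff(x$timepoints, x$baseline)
  ex <- x$scheme$edges_x; ey <- x$scheme$edges_y
  wl <- x$wavelengths
  xlab <- if (!is.null(wl) && !is.na(wl["x"]))
    sprintf("%s nm irradiance (mW/cm²)", wl["x"]) else "dose x (mW/cm²)"
  ylab <- if (!is.null(wl) && !is.na(wl["y"]))
    sprintf("%s nm irradiance (mW/cm²)", wl["y"]) else "dose y (mW/cm²)"
  old <- graphics::par(mfrow = c(1, length(timepoint)))
  on.exit(graphics::par(old))
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  rng <- range(unlist(lapply(x$stats[timepoint], function(s) s$mean)),
               na.rm = TRUE)
  half <- max(abs(rng - 1))
  for (lab in timepoint) {
    m <- t(x$stats[[lab]]$mean)  # image(): x = first index
    graphics::image(ex, ey, m, col = pal, zlim = c(1 - half, 1 + half),
                    xlab = xlab, ylab = ylab,
                    main = sprintf("mean fold change, %s", lab), ...)
    graphics::box()
  }
  invisible(x)
}
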