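#' Fit a polynomial irradiance-gradient model to beam-profile line scans
#'
#' Least-squares polynomial fit of measured irradiance against position along
#' one gradient axis of a dual-wavelength gradient laser beam. Replicate line
#' scans are pooled as independent points by default. When `degree = NULL`
#' the polynomial degree is chosen by Akaike's information criterion over
#' `candidates` (see [select_degree_aic()]).
#'
#' The design matrix is built on positions rescaled to `[-1, 1]`-order
#' magnitude (division by the largest absolute position) and solved by QR,
#' so that degrees up to 6 over millimetre-scale fields remain well
#' conditioned; coefficients and their covariance are transformed back to
#' the raw scale (mW/cm^2 per micron^k) for reporting.
#'
#' The model-selection score is the least-squares form
#' `AIC = n * log(RSS / n) + 2 * (degree + 2)`, counting the polynomial
#' coefficients plus the noise variance as parameters. RSS is floored at
#' `n * 1e-12 * mean(y^2)` so exactly interpolating fits have a finite
#' score and the lowest interpolating degree wins.
#'
#' @param position numeric, positions along the gradient axis (micron, >= 0).
#' @param irradiance numeric, measured irradiance (mW/cm^2, > 0), same
#'   length as `position`.
#' @param degree integer polynomial degree, or `NULL` to select by AIC.
#' @param wavelength numeric label of the laser line (nm), e.g. 1064 or 1270.
#' @param candidates integer vector of candidate degrees used when
#'   `degree = NULL`.
#' @param replicate optional replicate labels (only used when
#'   `pool = "means"`).
#' @param pool `"points"` pools all replicate points into one fit;
#'   `"means"` fits the per-position mean irradiance instead.
#' @return An object of class `"beam_fit"` with components `coefficients`
#'   (raw scale, ordered c0..cd), `degree`, `wavelength`, `rss`, `n`,
#'   `df_residual`, `covariance`, `aic` and, after AIC selection, an
#'   `aic_table` of the candidate degrees.
#' @examples
#' x <- seq(0, 1200, by = 20)
#' y <- 384.3 + 0.1546 * x - 7.934e-4 * x^2
#' fit <- fit_beam_profile(x, y, degree = 2, wavelength = 1064)
#' coef(fit)
#' predict(fit, c(0, 600, 1200))
#' @seealso [select_degree_aic()], [confidence_band()], [irradiance_map()]
#' @export
fit_beam_profile <- function(position, irradiance, degree = NULL,
                             wavelength = NA_real_, candidates = 0:6,
                             replicate = NULL, pool = c("points", "means")) {
  pool <- match.arg(pool)
  if (length(position) != length(irradiance))
    stop("'position' and 'irradiance' must have the same length")
  if (!all(is.finite(position)) || !all(is.finite(irradiance)))
    stop("positions and irradiances must be finite")
  if (any(irradiance <= 0))
    stop("irradiance values must be positive")
  if (pool == "means") {
    m <- tapply(irradiance, position, mean)
    position <- as.numeric(names(m))
    irradiance <- as.numeric(m)
  }
  if (is.null(degree))
    return(select_degree_aic(position, irradiance, candidates = candidates,
                             wavelength = wavelength))
  degree <- as.integer(degree)
  if (length(degree) != 1L || is.na(degree) || degree < 0L)
    stop("'degree' must be a single non-negative integer")
  .fit_poly(position, irradiance, degree, wavelength)
}

#' Select the polynomial degree of a gradient fit by AIC
#'
#' Fits every candidate degree by least squares and returns the fit with the
#' smallest AIC; exact ties are broken towards the lowest degree. Because
#' interpolating fits share the floored RSS, the parameter penalty makes the
#' lowest exactly-fitting degree the winner on noiseless data.
#'
#' @inheritParams fit_beam_profile
#' @param candidates non-empty integer vector of degrees to compare.
#' @return The winning `"beam_fit"`, carrying an `aic_table` data frame
#'   (`degree`, `rss`, `aic`) for all candidates.
#' @export
select_degree_aic <- function(position, irradiance, candidates = 0:6,
                              wavelength = NA_real_) {
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) == 0L || anyNA(candidates))
    stop("'candidates' must be a non-empty set of integer degrees")
  fits <- lapply(candidates, function(d)
    .fit_poly(position, irradiance, d, wavelength))
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  best <- fits[[which.min(aics)]]  # candidates ascending => ties go low
  best$aic_table <- data.frame(
    degree = candidates,
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    aic = aics
  )
  best
}

# Core least-squares polynomial fit on the scaled basis.
.fit_poly <- function(position, irradiance, degree, wavelength) {
  n <- length(position)
  n_distinct <- length(unique(position))
  if (n_distinct < degree + 1L)
    stop(sprintf(
      "degree %d requires at least %d distinct positions (got %d)",
      degree, degree + 1L, n_distinct))
  s <- max(abs(position), 1)
  X <- outer(position / s, 0:degree, `^`)
  qrX <- qr(X)
  if (qrX$rank < degree + 1L)
    stop("design matrix is rank deficient; reduce the degree")
  beta <- qr.coef(qrX, irradiance)
  fitted <- drop(X %*% beta)
  res <- irradiance - fitted
  rss <- sum(res^2)
  dfres <- n - (degree + 1L)
  sigma2 <- if (dfres > 0L) rss / dfres else NA_real_
  V <- chol2inv(qr.R(qrX))
  piv <- qrX$pivot
  Vs <- matrix(NA_real_, degree + 1L, degree + 1L)
  Vs[piv, piv] <- V
  cov_scaled <- if (dfres > 0L) sigma2 * Vs else Vs * NA_real_
  scl <- s^(0:degree)
  rss_floor <- n * 1e-12 * mean(irradiance^2)
  aic <- n * log(max(rss, rss_floor) / n) + 2 * (degree + 2)
  structure(list(
    coefficients = stats::setNames(beta / scl, paste0("c", 0:degree)),
    degree = degree,
    wavelength = wavelength,
    rss = rss,
    n = n,
    df_residual = dfres,
    sigma2 = sigma2,
    covariance = cov_scaled / tcrossprod(scl),
    scale = s,
    coef_scaled = beta,
    cov_scaled = cov_scaled,
    aic = aic,
    data = data.frame(position = position, irradiance = irradiance),
    fitted.values = fitted,
    residuals = res
  ), class = "beam_fit")
}

#' Evaluate a gradient polynomial at given positions
#'
#' Computes `sum(c_k * position^k)` by a numerically stable Horner scheme.
#' Accepts either a fitted [fit_beam_profile()] object or a bare coefficient
#' vector ordered `c0..cd`.
#'
#' @param object a `"beam_fit"` or a numeric coefficient vector.
#' @param position numeric positions (micron); must be finite.
#' @return Irradiance values (mW/cm^2), same length as `position`.
#' @export
evaluate_irradiance <- function(object, position) {
  coefs <- if (inherits(object, "beam_fit")) object$coefficients
           else as.numeric(object)
  if (length(coefs) == 0L) stop("empty coefficient vector")
  if (!all(is.finite(position))) stop("positions must be finite")
  .horner(coefs, position)
}

.horner <- function(coefs, x) {
  y <- rep(coefs[[length(coefs)]], length(x))
  if (length(coefs) > 1L)
    for (k in rev(seq_len(length(coefs) - 1L)))
      y <- y * x + coefs[[k]]
  y
}

#' Pointwise confidence band for the fitted gradient curve
#'
#' Delta-method band for the mean curve: at each position the standard error
#' is `sqrt(x' V x)` with `V` the parameter covariance, and the band is the
#' fitted value plus/minus a Student-t quantile with `n - (degree + 1)`
#' residual degrees of freedom. This is a confidence band for the fitted
#' mean, not a prediction band for new observations.
#'
#' @param fit a `"beam_fit"` with positive residual degrees of freedom.
#' @param positions numeric positions (micron).
#' @param level confidence level in (0, 1); default 0.95.
#' @return A data frame with columns `position`, `fit`, `lwr`, `upr`.
#' @export
confidence_band <- function(fit, positions, level = 0.95) {
  if (!inherits(fit, "beam_fit")) stop("'fit' must be a beam_fit")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must be a probability strictly between 0 and 1")
  p <- predict(fit, positions, interval = "confidence", level = level)
  cbind(data.frame(position = positions), p)
}

#' @rdname fit_beam_profile
#' @param object,x a `"beam_fit"` object.
#' @param interval `"none"` for point evaluation, `"confidence"` for a
#'   delta-method band for the mean curve.
#' @param level confidence level for `interval = "confidence"`.
#' @param ... unused.
#' @export
predict.beam_fit <- function(object, position, interval = c("none", "confidence"),
                             level = 0.95, ...) {
  interval <- match.arg(interval)
  if (missing(position)) position <- object$data$position
  if (!all(is.finite(position))) stop("positions must be finite")
  fit <- .horner(object$coefficients, position)
  if (interval == "none") return(fit)
  if (is.na(object$df_residual) || object$df_residual <= 0L)
    stop("saturated fit: no residual degrees of freedom for a confidence band")
  z <- position / object$scale
  X0 <- outer(z, 0:object$degree, `^`)
  se <- sqrt(pmax(rowSums((X0 %*% object$cov_scaled) * X0), 0))
  tq <- stats::qt(1 - (1 - level) / 2, df = object$df_residual)
  data.frame(fit = fit, lwr = fit - tq * se, upr = fit + tq * se)
}

#' @export
coef.beam_fit <- function(object, ...) object$coefficients

#' @export
vcov.beam_fit <- function(object, ...) object$covariance

#' @export
fitted.beam_fit <- function(object, ...) object$fitted.values

#' @export
residuals.beam_fit <- function(object, ...) object$residuals

#' @export
AIC.beam_fit <- function(object, ...) object$aic

#' @export
print.beam_fit <- function(x, digits = max(4L, getOption("digits") - 3L), ...) {
  wl <- if (is.na(x$wavelength)) "unlabelled" else paste0(x$wavelength, " nm")
  cat(sprintf("Gradient-beam polynomial fit (%s), degree %d\n", wl, x$degree))
  cat("Coefficients (mW/cm^2 per micron^k):\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("n = %d points, RSS = %.6g, AIC = %.4f\n", x$n, x$rss, x$aic))
  invisible(x)
}

#' @export
summary.beam_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$covariance), 0))
  tab <- cbind(Estimate = as.numeric(object$coefficients),
               `Std. Error` = se,
               `t value` = as.numeric(object$coefficients) / se)
  rownames(tab) <- names(object$coefficients)
  out <- list(fit = object, coefficients = tab,
              sigma = sqrt(object$sigma2), aic_table = object$aic_table)
  class(out) <- "summary.beam_fit"
  out
}

#' @export
print.summary.beam_fit <- function(x, digits = 4L, ...) {
  print(x$fit)
  cat("\nCoefficient table:\n")
  print(signif(x$coefficients, digits))
  if (is.finite(x$sigma))
    cat(sprintf("Residual standard error: %.4g on %d df\n",
                x$sigma, x$fit$df_residual))
  if (!is.null(x$aic_table)) {
    cat("\nAIC by candidate degree:\n")
    print(x$aic_table, row.names = FALSE)
  }
  invisible(x)
}

#' @rdname fit_beam_profile
#' @param band draw the 95% confidence band (requires residual df > 0).
#' @export
plot.beam_fit <- function(x, band = TRUE, ...) {
  d <- x$data
  xs <- seq(min(d$position), max(d$position), length.out = 200L)
  plot(d$position, d$irradiance, pch = 16, cex = 0.6, col = "grey40",
       xlab = "position (µm)", ylab = "irradiance (mW/cm²)",
       main = sprintf("Gradient fit, degree %d", x$degree), ...)
  graphics::lines(xs, predict(x, xs), lwd = 2, col = "firebrick")
  if (band && !is.na(x$df_residual) && x$df_residual > 0L) {
    cb <- predict(x, xs, interval = "confidence")
    graphics::lines(xs, cb$lwr, lty = 2, col = "firebrick")
    graphics::lines(xs, cb$upr, lty = 2, col = "firebrick")
  }
  invisible(x)
}

#' Published dual-beam gradient calibration coefficients
#'
#' Coefficient vectors of the reference polynomial calibrations of the two
#' orthogonal gradient beams: a quartic for the 1064 nm gradient along x and
#' a quadratic for the 1270 nm gradient along y, positions in micron and
#' irradiance in mW/cm^2. These serve as a known truth for simulations and
#' as a ready-made calibration for worked examples.
#'
#' @param wavelength `"1064"` or `"1270"`.
#' @return Numeric coefficient vector ordered `c0..cd`.
#' @examples
#' evaluate_irradiance(gradient_coefficients("1064"), 0)   # 384.3
#' evaluate_irradiance(gradient_coefficients("1270"), 0)   # 95.82
#' @export
gradient_coefficients <- function(wavelength = c("1064", "1270")) {
  switch(match.arg(as.character(wavelength), c("1064", "1270")),
    "1064" = c(c0 = 384.3, c1 = 0.1546, c2 = -7.934e-4,
               c3 = 9.238e-7, c4 = -3.934e-10),
    "1270" = c(c0 = 95.82, c1 = 2.091e-2, c2 = -4.679e-5))
}

#' Build a beam_fit from known coefficients
#'
#' Wraps a coefficient vector (for example [gradient_coefficients()]) as a
#' `"beam_fit"` so it can be evaluated and composed into an
#' [irradiance_map()]. Such a fit has no residual information, so no
#' confidence band is available.
#'
#' @param coefficients numeric vector ordered `c0..cd`.
#' @param wavelength numeric nm label.
#' @return A `"beam_fit"` with `rss = 0` and zero residual df.
#' @export
as_beam_fit <- function(coefficients, wavelength = NA_real_) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) == 0L || !all(is.finite(coefficients)))
    stop("'coefficients' must be a non-empty finite numeric vector")
  d <- length(coefficients) - 1L
  structure(list(
    coefficients = stats::setNames(coefficients, paste0("c", 0:d)),
    degree = d, wavelength = wavelength,
    rss = 0, n = d + 1L, df_residual = 0L, sigma2 = NA_real_,
    covariance = matrix(NA_real_, d + 1L, d + 1L),
    scale = 1, coef_scaled = coefficients,
    cov_scaled = matrix(NA_real_, d + 1L, d + 1L),
    aic = NA_real_,
    data = data.frame(position = numeric(0), irradiance = numeric(0)),
    fitted.values = numeric(0), residuals = numeric(0)
  ), class = "beam_fit")
}
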