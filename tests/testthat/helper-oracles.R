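# Independent brute-force oracles used to cross-check the vectorized
# implementations. Deliberately written as plain nested loops / direct
# integrals so they share no code with the package internals.

# Direct 3x3 convolution with replicate borders.
oracle_smooth <- function(m, sigma = 0.85) {
  g <- exp(-((-1:1)^2) / (2 * sigma^2))
  k <- outer(g, g); k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1L), nr)
      jj <- min(max(j + dj, 1L), nc)
      s <- s + k[di + 2L, dj + 2L] * m[ii, jj]
    }
    out[i, j] <- s
  }
  out
}

# Exhaustive per-pixel neighbourhood local-maximum search with row-major
# plateau deduplication. Returns a matrix of (row, col) 1-based calls.
oracle_detect <- function(sm, thr, window = 5L) {
  r <- window %/% 2L
  nr <- nrow(sm); nc <- ncol(sm)
  calls <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!(sm[i, j] > thr)) next
    nb <- sm[max(1L, i - r):min(nr, i + r), max(1L, j - r):min(nc, j + r)]
    if (sm[i, j] >= max(nb)) calls <- rbind(calls, c(i, j))
  }
  if (is.null(calls)) return(matrix(0L, 0L, 2L))
  keep <- rep(TRUE, nrow(calls))
  for (a in seq_len(nrow(calls))) {
    if (!keep[a]) next
    for (b in seq_len(nrow(calls))) {
      if (b <= a || !keep[b]) next
      if (max(abs(calls[a, ] - calls[b, ])) <= window - 1L) keep[b] <- FALSE
    }
  }
  calls[keep, , drop = FALSE]
}

# One-way ANOVA by explicit sums of squares.
oracle_anova <- function(groups) {
  y <- unlist(groups)
  g <- length(groups); N <- length(y)
  grand <- mean(y)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  Fv <- (ssb / (g - 1)) / (ssw / (N - g))
  list(F = Fv, df_between = g - 1, df_within = N - g,
       p = stats::pf(Fv, g - 1, N - g, lower.tail = FALSE),
       ssb = ssb, ssw = ssw)
}

# Studentized-range CDF by direct numerical integration of the standard
# double-integral representation (outer over the scale s = sqrt(chi2/df)).
oracle_ptukey <- function(q, k, df) {
  Rfun <- function(u) {
    if (u <= 0) return(0)
    k * stats::integrate(function(z)
      stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - u))^(k - 1),
      -Inf, Inf, rel.tol = 1e-10)$value
  }
  dens_s <- function(s)
    exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
          (df - 1) * log(s) - df * s^2 / 2)
  stats::integrate(Vectorize(function(s) dens_s(s) * Rfun(q * s)),
                   0, Inf, rel.tol = 1e-9)$value
}

# Exhaustive minimum-cost maximum-cardinality matching for small linking
# instances: baseline i may pair with frame j only when d[i, j] <= tol.
oracle_match <- function(d, tol) {
  nb <- nrow(d); nf <- ncol(d)
  best <- list(count = -1L, cost = Inf, assign = rep(NA_integer_, nb))
  recurse <- function(i, used, assign, count, cost) {
    if (i > nb) {
      if (count > best$count ||
          (count == best$count && cost < best$cost)) {
        best <<- list(count = count, cost = cost, assign = assign)
      }
      return(invisible())
    }
    recurse(i + 1L, used, assign, count, cost)   # leave i unmatched
    for (j in seq_len(nf)) {
      if (!used[j] && d[i, j] <= tol) {
        used[j] <- TRUE; assign[i] <- j
        recurse(i + 1L, used, assign, count + 1L, cost + d[i, j])
        used[j] <- FALSE; assign[i] <- NA_integer_
      }
    }
  }
  recurse(1L, logical(nf), rep(NA_integer_, nb), 0L, 0)
  best
}

# Reference irradiance map over the 1.2 mm field at 1.6 um/px.
reference_map <- function() {
  irradiance_map(as_beam_fit(gradient_coefficients("1064"), 1064),
                 as_beam_fit(gradient_coefficients("1270"), 1270),
                 pixel_size = 1.6, field_extent = c(1200, 1200))
}

# Render a single-cell frame directly (no generator machinery).
single_spot_frame <- function(nr, nc, cx, cy, amp, sigma, background = 0) {
  m <- matrix(background, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    m[i, j] <- m[i, j] +
      amp * exp(-(((j - 1) - cx)^2 + ((i - 1) - cy)^2) / (2 * sigma^2))
  }
  m
}
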