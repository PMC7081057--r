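test_that("noiseless polynomial truths are recovered exactly", {
  # straight line
  x <- seq(0, 90, by = 10)
  f <- fit_beam_profile(x, 2 + 3 * x, degree = 1)
  expect_equal(unname(coef(f)), c(2, 3), tolerance = 1e-10)
  expect_lt(f$rss, 1e-18)
  # constant
  f0 <- fit_beam_profile(1:10, rep(7, 10), degree = 0)
  expect_equal(unname(coef(f0)), 7)
  # quartic gradient truth from 61 noiseless samples, >= 4 significant figures
  eq1 <- gradient_coefficients("1064")
  x <- seq(0, 1200, by = 20)
  f4 <- fit_beam_profile(x, evaluate_irradiance(eq1, x), degree = 4,
                         wavelength = 1064)
  expect_equal(unname(coef(f4)), unname(eq1), tolerance = 1e-5)
})

test_that("underdetermined and invalid inputs are rejected", {
  expect_error(fit_beam_profile(c(0, 1), c(1, 2), degree = 3),
               "at least 4 distinct positions")
  expect_error(fit_beam_profile(c(0, 0, 0), c(1, 1.1, 0.9), degree = 1),
               "distinct positions")
  expect_error(fit_beam_profile(c(0, NA), c(1, 2), degree = 1), "finite")
  expect_error(fit_beam_profile(c(0, 1), c(-1, 2), degree = 1), "positive")
  expect_error(select_degree_aic(1:10, rexp(10) + 1, candidates = integer(0)),
               "non-empty")
})

test_that("AIC selection prefers the lowest exactly fitting degree", {
  x <- seq(0, 100, by = 5)
  y <- 5 + 2 * x - 0.03 * x^2
  f <- select_degree_aic(x, y, candidates = 1:6)
  expect_identical(f$degree, 2L)
  expect_identical(nrow(f$aic_table), 6L)
  expect_identical(f$aic_table$degree[which.min(f$aic_table$aic)], 2L)
})

test_that("AIC matches the independent least-squares formula on noisy data", {
  set.seed(11)
  x <- rep(seq(0, 1200, by = 40), times = 3)
  y <- evaluate_irradiance(gradient_coefficients("1064"), x) *
    (1 + rnorm(length(x), 0, 0.02))
  for (d in c(1L, 3L, 5L)) {
    f <- fit_beam_profile(x, y, degree = d)
    rss <- sum((y - evaluate_irradiance(f, x))^2)
    n <- length(x)
    expect_equal(f$aic, n * log(rss / n) + 2 * (d + 2), tolerance = 1e-8)
  }
})

test_that("Horner evaluation agrees with direct term-by-term summation", {
  eq1 <- gradient_coefficients("1064")
  xs <- c(0, 1, 17.5, 600, 1200)
  direct <- vapply(xs, function(x) sum(eq1 * x^(0:4)), numeric(1))
  expect_equal(evaluate_irradiance(eq1, xs), direct, tolerance = 1e-9)
  expect_identical(evaluate_irradiance(c(0, 0, 0), c(-5, 0, 42)), c(0, 0, 0))
})

test_that("evaluation is linear in the coefficients", {
  set.seed(3)
  f <- runif(5, -1, 1); g <- runif(5, -1, 1)
  xs <- runif(20, 0, 10)
  expect_equal(evaluate_irradiance(2.5 * f + -1.3 * g, xs),
               2.5 * evaluate_irradiance(f, xs) -
                 1.3 * evaluate_irradiance(g, xs),
               tolerance = 1e-12)
})

test_that("confidence band is a correct delta-method band", {
  set.seed(21)
  # constant fit: band half-width must equal the one-sample t CI, t*s/sqrt(n)
  y <- rnorm(25, 10, 2)
  f0 <- fit_beam_profile(seq_len(25), y, degree = 0)
  cb <- confidence_band(f0, c(1, 13), level = 0.95)
  half <- qt(0.975, 24) * sd(y) / sqrt(25)
  expect_equal(cb$upr - cb$fit, rep(half, 2), tolerance = 1e-10)
  expect_equal(cb$fit, rep(mean(y), 2), tolerance = 1e-10)

  # containment and symmetry on a generic fit
  x <- rep(seq(0, 100, by = 10), 3)
  f <- fit_beam_profile(x, 50 + x + rnorm(length(x)), degree = 2)
  pos <- seq(0, 100, by = 7)
  cb <- confidence_band(f, pos, level = 0.95)
  expect_true(all(cb$lwr <= cb$fit & cb$fit <= cb$upr))
  expect_equal(cb$upr - cb$fit, cb$fit - cb$lwr, tolerance = 1e-12)

  # monotone in the confidence level
  cb99 <- confidence_band(f, pos, level = 0.99)
  expect_true(all(cb99$upr - cb99$lwr >= cb$upr - cb$lwr))

  # saturated fits have no band
  fsat <- fit_beam_profile(c(0, 1), c(1, 2), degree = 1)
  expect_error(confidence_band(fsat, 0.5), "saturated")
  expect_error(confidence_band(f, pos, level = 1), "probability")
})

test_that("replicate pooling and per-position means are both supported", {
  x <- rep(c(0, 10, 20, 30), each = 2)
  y <- c(1, 3, 11, 13, 21, 23, 31, 33)  # per-position means 2, 12, 22, 32
  fm <- fit_beam_profile(x, y, degree = 1, pool = "means")
  expect_equal(unname(coef(fm)), c(2, 1), tolerance = 1e-10)
  fp <- fit_beam_profile(x, y, degree = 1, pool = "points")
  expect_identical(fp$n, 8L)
  expect_gt(fp$rss, 0)
})

test_that("calibration fits round-trip through JSON with full precision", {
  set.seed(5)
  x <- rep(seq(0, 1200, by = 30), 2)
  y <- evaluate_irradiance(gradient_coefficients("1270"), x) *
    (1 + rnorm(length(x), 0, 0.02))
  f <- select_degree_aic(x, y, wavelength = 1270)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(f, path)
  f2 <- read_calibration(path)
  expect_identical(f2$degree, f$degree)
  expect_equal(coef(f2), coef(f), tolerance = 1e-15)
  expect_equal(f2$aic, f$aic, tolerance = 1e-12)
  expect_equal(f2$aic_table$aic, f$aic_table$aic, tolerance = 1e-12)
  pos <- c(0, 333.3, 1200)
  expect_equal(confidence_band(f2, pos), confidence_band(f, pos),
               tolerance = 1e-10)
})
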