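make_det <- function(col, row, intensity = rep(100, length(col)),
                     label = NA_character_) {
  data.frame(col = col, row = row, intensity_raw = intensity,
             intensity_smoothed = intensity, frame_label = label)
}

test_that("identical detections at every timepoint keep every cell", {
  d <- make_det(c(3, 20, 40), c(5, 18, 33), c(100, 200, 300))
  tr <- track_cells(list(pre = d, `1min` = d, `5min` = d))
  expect_identical(nrow(tr), 3L)
  expect_identical(tr$col_1min, tr$col)
  expect_identical(tr$row_5min, tr$row)
  tr <- compute_fold_changes(tr)
  expect_identical(tr$fold_pre, rep(1, 3))
  expect_equal(tr$fold_1min, rep(1, 3))
  expect_equal(tr$fold_5min, rep(1, 3))
})

test_that("a cell displaced beyond the tolerance is dropped", {
  pre <- make_det(c(10, 30), c(10, 30))
  moved <- make_det(c(10, 33), c(10, 30))  # second cell shifted 3 px
  tr <- track_cells(list(pre = pre, `1min` = moved), tolerance_px = 2)
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$col, 10)
  # displacement exactly at the tolerance is retained
  tr2 <- track_cells(list(pre = pre, `1min` = moved), tolerance_px = 3)
  expect_identical(nrow(tr2), 2L)
})

test_that("jittered populations with dropouts match the exhaustive matching", {
  set.seed(77)
  # 45 cells on a jittered grid: separations >> tolerance, so unambiguous
  g <- expand.grid(col = seq(10, 170, by = 20), row = seq(10, 90, by = 20))
  base <- make_det(g$col + runif(45, -3, 3), g$row + runif(45, -3, 3))
  lost <- sample(45, 5)
  later <- base[-lost, ]
  later$col <- later$col + runif(40, -1, 1)
  later$row <- later$row + runif(40, -1, 1)
  tr <- track_cells(list(pre = base, post = later), tolerance_px = 2)
  expect_identical(nrow(tr), 40L)
  expect_true(all(tr$col %in% base$col[-lost]))
  # greedy assignment equals the optimal exhaustive matching on a small
  # separable case (wide spacing, sub-tolerance jitter, one spurious det)
  set.seed(12)
  b2 <- make_det(c(0, 20, 40, 0, 20), c(0, 0, 0, 20, 20))
  f2 <- make_det(b2$col + runif(5, -1, 1), b2$row + runif(5, -1, 1))
  f2 <- rbind(f2, make_det(60, 60))
  d <- sqrt(outer(b2$col, f2$col, `-`)^2 + outer(b2$row, f2$row, `-`)^2)
  opt <- oracle_match(d, tol = 2)
  tr2 <- track_cells(list(pre = b2, post = f2), tolerance_px = 2)
  expect_identical(nrow(tr2), opt$count)
  expect_identical(opt$count, 5L)
  # and the greedy pairing reproduces the optimal one pair by pair
  expect_equal(tr2$col_post, f2$col[opt$assign], tolerance = 1e-12)
})

test_that("fold changes are baseline-normalised ratios", {
  pre <- make_det(5, 5, 200)
  one <- make_det(5, 5, 100)
  five <- make_det(5, 5, 260)
  tr <- compute_fold_changes(track_cells(list(pre = pre, `1min` = one,
                                              `5min` = five)))
  expect_identical(tr$fold_pre, 1)
  expect_equal(tr$fold_1min, 0.5)
  expect_equal(tr$fold_5min, 1.3)
  # optional per-timepoint background subtraction enters the ratio
  tr2 <- compute_fold_changes(track_cells(list(pre = pre, `1min` = one)),
                              background = c(pre = 100, `1min` = 50))
  expect_equal(tr2$fold_1min, 0.5)
})

test_that("non-positive baseline intensities are excluded with a warning", {
  pre <- make_det(c(5, 20), c(5, 20), c(0, 150))
  one <- make_det(c(5, 20), c(5, 20), c(10, 75))
  tr <- track_cells(list(pre = pre, `1min` = one))
  expect_warning(out <- compute_fold_changes(tr), "non-positive baseline")
  expect_identical(nrow(out), 1L)
  expect_equal(out$fold_1min, 0.5)
  expect_identical(nrow(attr(out, "excluded")), 1L)
})

test_that("duplicate timepoint labels and bad baselines are rejected", {
  d <- make_det(1, 1)
  expect_error(track_cells(stats::setNames(list(d, d), c("a", "a"))),
               "duplicate")
  expect_error(track_cells(list(a = d, b = d), baseline = "zz"),
               "not present")
})

test_that("doses are assigned from the baseline position", {
  m <- reference_map()
  pre <- make_det(c(0, 100), c(0, 200), c(100, 100))
  one <- make_det(c(0, 100), c(0, 200), c(90, 110))
  tr <- assign_doses(compute_fold_changes(track_cells(list(pre = pre,
                                                           `1min` = one))), m)
  expect_equal(tr$dose_x[1], 384.3)
  expect_equal(tr$dose_y[1], 95.82)
  expect_equal(tr$dose_x[2],
               evaluate_irradiance(gradient_coefficients("1064"), 160))
  expect_true(all(tr$in_field))
})
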