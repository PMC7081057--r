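make_tracks <- function(dose_x, dose_y, fold_1, fold_5 = NULL,
                        control = FALSE) {
  n <- max(length(dose_x), length(fold_1))
  out <- data.frame(cell_id = seq_len(n), col = rep(0L, n), row = rep(0L, n),
                    fold_pre = rep(1, n),
                    fold_1min = fold_1,
                    dose_x = rep(dose_x, length.out = n),
                    dose_y = rep(dose_y, length.out = n),
                    in_field = rep(!is.na(dose_x), length.out = n),
                    control = rep(control, length.out = n))
  if (!is.null(fold_5)) out$fold_5min <- fold_5
  structure(out, baseline = "pre",
            timepoints = c("pre", "1min", if (!is.null(fold_5)) "5min"),
            class = c("cell_tracks", "data.frame"))
}

test_that("bin assignment is half-open with the top edge closed", {
  sch <- dose_bin_scheme(c(0, 10, 20), c(0, 10, 20))
  tr <- make_tracks(dose_x = c(10, 20, 5), dose_y = c(5, 20, 25),
                    fold_1 = c(0.8, 0.9, 1.0))
  dr <- dose_response(tr, scheme = sch)
  # dose exactly on an interior edge goes to the higher bin
  expect_identical(dr$assignments$bin_x[dr$assignments$cell_id == 1L], 2L)
  # the topmost edge is closed
  expect_identical(dr$assignments$bin_x[dr$assignments$cell_id == 2L], 2L)
  expect_identical(dr$assignments$bin_y[dr$assignments$cell_id == 2L], 2L)
  # out-of-range cells are excluded and counted
  expect_identical(unname(dr$counts["in_range"]), 2L)
  expect_identical(unname(dr$counts["out_of_range"]), 1L)
  expect_error(dose_bin_scheme(c(1, 1), c(0, 1)), "ascending")
})

test_that("an empty track list yields an all-empty 25-group grid", {
  sch <- dose_bin_scheme(seq(0, 50, 10), seq(0, 50, 10))
  tr <- make_tracks(dose_x = numeric(0), dose_y = numeric(0),
                    fold_1 = numeric(0))
  dr <- dose_response(tr, scheme = sch)
  expect_identical(dim(summarize_grid(dr, "1min")$n), c(5L, 5L))
  expect_true(all(summarize_grid(dr, "1min")$n == 0L))
  expect_true(all(is.na(summarize_grid(dr, "1min")$mean)))
})

test_that("group summaries are means and SEMs of member fold changes", {
  sch <- dose_bin_scheme(c(0, 10), c(0, 10))
  tr <- make_tracks(dose_x = c(5, 5), dose_y = c(5, 5),
                    fold_1 = c(0.5, 1.5))
  s <- summarize_grid(dose_response(tr, scheme = sch), "1min")
  expect_equal(s$mean[1, 1], 1.0)
  expect_equal(s$sem[1, 1], 0.5)
  expect_identical(s$n[1, 1], 2L)
  # identical fold changes give SEM 0 in every occupied group
  tr2 <- make_tracks(dose_x = runif(30, 0, 10), dose_y = runif(30, 0, 10),
                     fold_1 = rep(0.8, 30))
  s2 <- summarize_grid(dose_response(tr2, scheme = sch), "1min")
  expect_equal(s2$mean[1, 1], 0.8)
  expect_equal(s2$sem[1, 1], 0)
})

test_that("summaries are invariant under cell ordering and counts conserved", {
  set.seed(55)
  n <- 200
  tr <- make_tracks(dose_x = runif(n, 0, 100), dose_y = runif(n, 0, 100),
                    fold_1 = rnorm(n, 1, 0.1))
  sch <- dose_bin_scheme(seq(0, 90, length.out = 6), seq(0, 90, length.out = 6))
  dr1 <- dose_response(tr, scheme = sch)
  perm <- sample(n)
  tr2 <- tr[perm, ]
  tr2$cell_id <- seq_len(n)
  attributes(tr2)[c("baseline", "timepoints")] <-
    attributes(tr)[c("baseline", "timepoints")]
  class(tr2) <- class(tr)
  dr2 <- dose_response(tr2, scheme = sch)
  expect_equal(summarize_grid(dr1, "1min"), summarize_grid(dr2, "1min"))
  expect_equal(unname(dr1$counts["in_range"] + dr1$counts["out_of_range"]),
               n)
})

test_that("one-way ANOVA reproduces the hand-computed decomposition", {
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  a <- one_way_anova(groups)
  # SS_between = 6 (MS 3), SS_within = 6 (MS 1), df = (2, 6) -> F = 3
  expect_equal(a$F, 3, tolerance = 1e-12)
  o <- oracle_anova(groups)
  expect_equal(a$F, o$F, tolerance = 1e-12)
  expect_equal(c(a$df_between, a$df_within), c(2, 6))
  expect_equal(a$p_value, o$p, tolerance = 1e-12)
  expect_equal(o$ssb, 6)
  expect_equal(o$ssw, 6)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(2)
  g1 <- rnorm(12, 0, 1); g2 <- rnorm(15, 0.4, 1)
  a <- one_way_anova(list(g1, g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "identical")
  expect_error(one_way_anova(list(1, c(1, 2))), "at least 2 observations")
  expect_error(one_way_anova(list(c(1, 2))), "at least 2 groups")
  expect_error(one_way_anova(list(c(1, 1), c(2, 2))), "within-group variance")
})

test_that("Tukey HSD flags only genuinely shifted pairs", {
  set.seed(42)
  base <- rnorm(20)
  groups <- list(a = base, b = base + rnorm(20, 0, 0.3),
                 c = base + 10)  # 10 pooled-sd shift
  res <- tukey_hsd(groups, alpha = 0.05)
  tk <- res$tukey
  expect_identical(nrow(tk), 3L)
  expect_true(tk$significant[tk$group_i == "a" & tk$group_j == "c"])
  expect_true(tk$significant[tk$group_i == "b" & tk$group_j == "c"])
  expect_false(tk$significant[tk$group_i == "a" & tk$group_j == "b"])
  # identical groups: adjusted p of 1 and no significance
  same <- list(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4), z = c(1, 2, 3.5, 4))
  res2 <- tukey_hsd(same)
  expect_gt(min(res2$tukey$adj_p[1]), 0.999)
  expect_false(any(res2$tukey$significant[res2$tukey$adj_p > 0.999]))
})

test_that("Tukey adjusted p matches the studentized-range quadrature", {
  set.seed(7)
  groups <- lapply(c(0, 0.3, 0.8, 0.1), function(m) rnorm(10, m, 1))
  res <- tukey_hsd(groups)
  k <- length(groups); df <- res$anova$df_within
  for (i in seq_len(nrow(res$tukey))) {
    p_orc <- 1 - oracle_ptukey(res$tukey$q[i], k, df)
    expect_equal(res$tukey$adj_p[i], p_orc, tolerance = 1e-4)
  }
})

test_that("Tukey adjusted p never undercuts the unadjusted pairwise p", {
  set.seed(19)
  for (rep in 1:5) {
    groups <- lapply(rnorm(4, 1, 0.2), function(m) rnorm(8, m, 0.3))
    res <- tukey_hsd(groups)
    tk <- res$tukey
    # unadjusted pairwise t on the same pooled MS_within and df
    msw <- res$anova$ms_within; dfw <- res$anova$df_within
    for (i in seq_len(nrow(tk))) {
      gi <- groups[[as.integer(sub("group", "", tk$group_i[i]))]]
      gj <- groups[[as.integer(sub("group", "", tk$group_j[i]))]]
      tstat <- abs(mean(gi) - mean(gj)) /
        sqrt(msw * (1 / length(gi) + 1 / length(gj)))
      p_raw <- 2 * pt(-tstat, dfw)
      expect_gte(tk$adj_p[i] + 1e-12, p_raw)
    }
  }
})

test_that("control comparisons report suppression direction correctly", {
  set.seed(101)
  sch <- dose_bin_scheme(c(0, 10, 20), c(0, 10))
  supp <- make_tracks(dose_x = runif(40, 0, 10), dose_y = runif(40, 0, 10),
                      fold_1 = rnorm(40, 0.7, 0.05))
  norm <- make_tracks(dose_x = runif(40, 10, 20), dose_y = runif(40, 0, 10),
                      fold_1 = rnorm(40, 1, 0.05))
  ctrl <- make_tracks(dose_x = NA_real_, dose_y = NA_real_,
                      fold_1 = rnorm(40, 1, 0.05), control = TRUE)
  tr <- rbind(supp, norm, ctrl)
  tr$cell_id <- seq_len(nrow(tr))
  attributes(tr)[c("baseline", "timepoints")] <- list("pre", c("pre", "1min"))
  class(tr) <- c("cell_tracks", "data.frame")
  dr <- dose_response(tr, scheme = sch)
  vc <- dr$comparisons[["1min"]]$vs_control
  expect_identical(nrow(vc), 2L)
  sig <- vc[vc$significant, ]
  expect_identical(nrow(sig), 1L)  # only the suppressed bin differs
  expect_identical(unname(dr$counts["control"]), 40L)
})
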