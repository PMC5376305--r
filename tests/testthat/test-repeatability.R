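test_that("ROI means weight voxels as specified", {
  m <- array(c(10, 20), c(2, 1, 1))
  expect_equal(roi_mean(m, array(c(1, 1), c(2, 1, 1))), 15)
  expect_equal(roi_mean(m, array(c(0.8, 0.2), c(2, 1, 1))), 12)
  cmap <- array(7, c(3, 3, 2))
  expect_equal(roi_mean(cmap, array(runif(18), c(3, 3, 2))), 7)
  expect_error(roi_mean(m, array(0, c(2, 1, 1))), "empty ROI")
  ## non-finite voxels (unsolved) are excluded
  m[2] <- NA
  expect_equal(roi_mean(m, array(c(1, 1), c(2, 1, 1))), 10)
})

test_that("roi_from_masks zeroes sub-threshold GM and unsolved voxels", {
  gm <- array(c(0.9, 0.4, 0.8, 0.7), c(4, 1, 1))
  solved <- array(c(TRUE, TRUE, FALSE, TRUE), c(4, 1, 1))
  roi <- roi_from_masks("x", array(1, c(4, 1, 1)), gm, solved)
  expect_equal(as.numeric(roi$weights), c(0.9, 0, 0, 0.7))
})

test_that("within-subject statistics match the hand-computed example", {
  ws <- within_subject_stats(c(10, 20), c(12, 18))
  expect_equal(ws$dsd, sd(c(-2, 2)), tolerance = 1e-12)
  expect_equal(ws$wssd, 2, tolerance = 1e-12)
  expect_equal(ws$wscv, 14.85, tolerance = 1e-3)
  ## log10 approximation
  ws_log <- within_subject_stats(10^c(1, 1.2), 10^c(1.058, 1.142),
                                 scale = "log10")
  expect_equal(ws_log$wscv, 100 * (10^ws_log$wssd - 1), tolerance = 1e-12)
  expect_equal(100 * (10^0.041 - 1), 9.9, tolerance = 1e-2)
  ## identical tests give zeros
  a <- c(3, 5, 8)
  z <- within_subject_stats(a, a)
  expect_equal(c(z$dsd, z$wssd, z$wscv), c(0, 0, 0))
})

test_that("between-subject CV matches hand computation and is scale-free", {
  expect_equal(between_subject_cv(c(10, 12, 20, 18)), 31.74,
               tolerance = 1e-3)
  expect_equal(between_subject_cv(rep(4, 5)), 0)
  x <- c(10, 12, 20, 18)
  expect_equal(between_subject_cv(3.7 * x), between_subject_cv(x),
               tolerance = 1e-12)
  ws <- within_subject_stats(x[1:2], x[3:4])
  expect_equal(within_subject_stats(5 * x[1:2], 5 * x[3:4])$wscv, ws$wscv,
               tolerance = 1e-12)
})

test_that("scale decision keeps normal data and logs proportional error", {
  ## proportional differences force a Kendall rejection -> log10
  set.seed(9)
  means <- seq(20, 120, length.out = 6)
  diffs <- 0.2 * means + rnorm(6, 0, 0.05)
  dec <- scale_decision(diffs, means)
  expect_equal(dec$scale, "log10")
  expect_lt(dec$kendall_p, 0.05)
  ## all-zero differences are degenerate -> original
  dec0 <- scale_decision(rep(0, 5), c(10, 20, 30, 40, 50))
  expect_equal(dec0$scale, "original")
  expect_match(dec0$note, "degenerate")
  ## i.i.d. normal differences keep the original scale in >= 90% of runs
  set.seed(42)
  keep <- replicate(200, {
    d <- rnorm(6)
    m <- runif(6, 50, 150)
    scale_decision(d, m)$scale == "original"
  })
  expect_gte(mean(keep), 0.90)
})

test_that("Holm-corrected ROI comparison finds real shifts, not identity", {
  set.seed(13)
  base <- matrix(rnorm(10 * 2, 100, 1), 10, 2)
  expect_false(any(compare_rois(cbind(base[, 1], base[, 1] +
                                        rnorm(10, 0, 1e-6)))$significant))
  shifted <- cbind(a = base[, 1], b = base[, 1] + 50 + rnorm(10, 0, 0.1))
  expect_true(compare_rois(shifted)$significant["a", "b"])
  ## Holm never reports more discoveries than uncorrected testing
  v <- matrix(rnorm(8 * 5, 100, 10), 8, 5)
  cr <- compare_rois(v)
  expect_lte(sum(cr$p_adj < 0.05, na.rm = TRUE),
             sum(cr$p_raw < 0.05, na.rm = TRUE))
})

test_that("the repeatability report covers the three test combinations", {
  set.seed(21)
  subj <- paste0("s", 1:6)
  grid <- expand.grid(subject = subj, protocol = c("LHO", "HHO"),
                      test = c("A", "B"), roi = c("GM", "HIP"),
                      estimate = c("M", "OEF"), stringsAsFactors = FALSE)
  grid$value <- rnorm(nrow(grid), 100, 10)
  rep_tab <- repeatability_report(grid)
  expect_setequal(unique(rep_tab$combination),
                  c("AB_LHO", "AB_HHO", "A_LHO_vs_HHO"))
  expect_equal(nrow(rep_tab), 2 * 2 * 3)
  expect_true(all(rep_tab$wscv >= 0) && all(rep_tab$bscv >= 0))
  ## cross-check one cell against the direct computation
  cell <- rep_tab[rep_tab$estimate == "M" & rep_tab$roi == "GM" &
                    rep_tab$combination == "AB_LHO", ]
  a <- grid$value[grid$estimate == "M" & grid$roi == "GM" &
                    grid$protocol == "LHO" & grid$test == "A"]
  b <- grid$value[grid$estimate == "M" & grid$roi == "GM" &
                    grid$protocol == "LHO" & grid$test == "B"]
  dec <- scale_decision(a - b, (a + b) / 2)
  expect_equal(cell$wscv, within_subject_stats(a, b, dec$scale)$wscv)
})
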