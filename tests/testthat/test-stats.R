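test_that("Kruskal-Wallis matches direct rank arithmetic and is rank-invariant", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3))),
               list(H = 0, p = 1), tolerance = 1e-12)
  g <- list(c(1, 2, 3), c(4, 5, 6))
  kw <- kruskal_wallis(g)
  # direct rank computation: ranks 1..6, no ties
  N <- 6
  R1 <- sum(1:3); R2 <- sum(4:6)
  H_or <- 12 / (N * (N + 1)) * (R1^2 / 3 + R2^2 / 3) - 3 * (N + 1)
  expect_equal(kw$H, H_or, tolerance = 1e-10)
  expect_equal(kw$p, stats::pchisq(H_or, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # invariance under a monotone transform of the pooled data
  kw2 <- kruskal_wallis(lapply(g, function(x) exp(x) + 100))
  expect_equal(kw$H, kw2$H, tolerance = 1e-12)
})

test_that("the pooled t test matches the closed-form hand computation", {
  expect_equal(unpaired_ttest(c(5, 5, 5), c(5, 5, 5)), list(t = 0, p_raw = 1))
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  tt <- unpaired_ttest(a, b)
  sp2 <- ((2) * var(a) + (2) * var(b)) / 4
  t_or <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(tt$t, t_or, tolerance = 1e-12)
  expect_equal(tt$p_raw, 2 * stats::pt(abs(t_or), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # swapping the groups flips the sign and keeps p
  ts <- unpaired_ttest(b, a)
  expect_equal(ts$t, -tt$t, tolerance = 1e-12)
  expect_equal(ts$p_raw, tt$p_raw, tolerance = 1e-12)
})

test_that("multiplicity correction multiplies and caps at 1", {
  expect_equal(correct_multiplicity(0.03, 1, 1), 0.03)
  expect_equal(correct_multiplicity(0.001, 6, 8), 0.048)
  expect_equal(correct_multiplicity(0.2, 10, 3), 1)
  expect_equal(correct_multiplicity(c(0.001, 0.5), 6, 8), c(0.048, 1))
})

test_that("Cohen's d uses the n1+n2 pooled denominator", {
  expect_equal(cohens_d(c(3, 4, 5), c(2, 4, 6)), 0)
  a <- c(0, 1); b <- c(2, 3)
  # sp^2 = ((1)(.5) + (1)(.5)) / 4 = .25 -> d = (0.5 - 2.5)/0.5 = -4
  expect_equal(cohens_d(a, b), -4, tolerance = 1e-12)
  expect_equal(cohens_d(b, a), 4, tolerance = 1e-12)
  # textbook denominator option
  expect_equal(cohens_d(a, b, denominator = "n1+n2-2"),
               -2 / sqrt(0.5), tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)))
})

# null record table: one metric with no method effect
null_records <- function(methods, n_maps = 4, n_per = 25, seed = 1) {
  set.seed(seed)
  expand_rows <- expand.grid(threshold = methods,
                             map = paste0("map", seq_len(n_maps)),
                             i = seq_len(n_per), stringsAsFactors = FALSE)
  data.frame(pdav_percent = abs(rnorm(nrow(expand_rows), 50, 20)),
             dcm_mm = abs(rnorm(nrow(expand_rows), 4, 1.5)),
             dsc = runif(nrow(expand_rows)),
             map = expand_rows$map, threshold = expand_rows$threshold,
             motion = "NoMoCo", smoothing = "Blur06", regression = "Std")
}

test_that("stage summaries report zero percent-better on null data", {
  rec <- null_records(c("Bon", "FDR", "Clst", "AMPLE"), seed = 7)
  res <- summarize_stage(rec, "threshold", "dsc")
  expect_true(all(res$summary$percent_better >= 0 &
                  res$summary$percent_better <= 100))
  expect_identical(nrow(res$comparisons), 6L * 4L)  # pairs x maps
  # at most one method is declared better per comparison
  expect_true(all(is.na(res$comparisons$better) |
                  res$comparisons$better %in% c(res$comparisons$method_a,
                                                res$comparisons$method_b)))
})

test_that("a planted reproducibility advantage is detected as highest percent-better", {
  rec <- null_records(c("Blur00", "Blur06", "Blur12"), n_per = 40, seed = 13)
  names(rec)[names(rec) == "threshold"] <- "smoothing_method"
  rec$smoothing <- rec$smoothing_method
  # deflate PDAV for Blur12 by construction
  rec$pdav_percent[rec$smoothing == "Blur12"] <-
    rec$pdav_percent[rec$smoothing == "Blur12"] * 0.3
  res <- summarize_stage(rec, "smoothing", "pdav_percent")
  s <- res$summary
  expect_equal(s$method[which.max(s$percent_better)], "Blur12")
  expect_equal(max(s$percent_better), 100)
  expect_lt(res$kruskal$p, 0.001)
})

test_that("direction of 'better' respects each metric", {
  rec <- null_records(c("A", "B"), n_per = 50, seed = 3)
  names(rec)[names(rec) == "threshold"] <- "motion2"
  rec$motion <- rec$motion2
  rec$dsc[rec$motion == "B"] <- rec$dsc[rec$motion == "B"] + 2  # higher DSC better
  res <- summarize_stage(rec, "motion", "dsc")
  sB <- res$summary[res$summary$method == "B", ]
  expect_equal(sB$percent_better, 100)
  rec$dcm_mm[rec$motion == "B"] <- rec$dcm_mm[rec$motion == "B"] + 20 # higher DCM worse
  res2 <- summarize_stage(rec, "motion", "dcm_mm")
  expect_equal(res2$summary$percent_better[res2$summary$method == "A"], 100)
  expect_equal(res2$summary$percent_better[res2$summary$method == "B"], 0)
})
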