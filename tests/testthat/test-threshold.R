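test_that("one-sided p-values behave as an upper tail and match quadrature", {
  expect_equal(p_from_t(0, 30), 0.5)
  ts <- seq(-3, 6, by = 0.5)
  expect_true(all(diff(p_from_t(ts, 30)) < 0))
  # quadrature oracle for t = 2, dof = 60
  dens <- function(x, v) gamma((v + 1) / 2) / (sqrt(v * pi) * gamma(v / 2)) *
    (1 + x^2 / v)^(-(v + 1) / 2)
  p_or <- stats::integrate(dens, 2, Inf, v = 60, rel.tol = 1e-12)$value
  expect_equal(p_from_t(2, 60), p_or, tolerance = 1e-8)
})

test_that("Bonferroni activation uses a strict corrected threshold", {
  dm <- c(10, 10, 10)
  mask <- array(TRUE, dm)
  dof <- 40
  t_for_p <- function(p) stats::qt(p, dof, lower.tail = FALSE)
  tmap <- array(0, dm)
  tmap[1, 1, 1] <- t_for_p(1e-5)   # p * 1000 = .01, not < .01
  tmap[2, 1, 1] <- t_for_p(9e-6)   # p * 1000 = .009 < .01
  act <- bonferroni_threshold(tmap, dof, mask, alpha = 0.01)
  expect_false(act$active[1, 1, 1])
  expect_true(act$active[2, 1, 1])
  # a single-voxel mask reduces to the uncorrected threshold
  m1 <- array(FALSE, dm); m1[5, 5, 5] <- TRUE
  t1 <- array(0, dm); t1[5, 5, 5] <- t_for_p(0.009)
  expect_true(bonferroni_threshold(t1, dof, m1, alpha = 0.01)$active[5, 5, 5])
})

test_that("BH adjustment matches an exhaustive step-up oracle", {
  expect_equal(fdr_adjust(rep(0.03, 7)), rep(0.03, 7))
  p <- c(0.001, 0.008, 0.039, 0.041)
  # explicit step-up: q_(i) = min over j >= i of m p_(j) / j
  m <- length(p)
  ord <- order(p)
  q_or <- numeric(m)
  for (i in seq_len(m)) {
    q_or[ord[i]] <- min(sapply(i:m, function(j) m * p[ord[j]] / j))
  }
  expect_equal(fdr_adjust(p), pmin(1, q_or), tolerance = 1e-12)
  # adjusted values are monotone in p
  expect_true(all(diff(fdr_adjust(sort(runif(20))))>= 0))
})

test_that("smoothness estimation tracks the applied kernel", {
  dm <- c(24, 24, 18)
  mask <- array(TRUE, dm)
  set.seed(6)
  nt <- 30
  make_res <- function(fwhm) {
    r <- array(rnorm(prod(dm) * nt), c(dm, nt))
    if (fwhm > 0) for (t in 1:nt) {
      r[, , , t] <- fmritrt:::gaussian_smooth_3d(r[, , , t], fwhm, 4)
    }
    r
  }
  est0 <- estimate_smoothness(make_res(0), mask, 4)
  expect_lt(max(est0$fwhm_mm), 1.5 * 4)
  est8 <- estimate_smoothness(make_res(8), mask, 4)
  expect_equal(est8$fwhm_geom_mm, 8, tolerance = 0.2)   # within 8 +/- 1.6
  est12 <- estimate_smoothness(make_res(12), mask, 4)
  expect_gt(est12$fwhm_geom_mm, est8$fwhm_geom_mm)
  expect_gt(est8$fwhm_geom_mm, est0$fwhm_geom_mm)
})

test_that("the Monte-Carlo cluster-size table is deterministic and sane", {
  cfg <- ideal_config(grid = c(16, 16, 12))
  mask <- brain_mask(cfg)
  tab <- cluster_size_threshold(mask, 6, 4, alpha = c(0.01, 0.05, 1),
                                n_iter = 200, seed = 17)
  expect_identical(tab$k[tab$alpha == 1], 1L)
  # k non-increasing as alpha grows
  expect_true(all(diff(tab$k[order(tab$alpha)]) <= 0))
  tab2 <- cluster_size_threshold(mask, 6, 4, alpha = c(0.01, 0.05, 1),
                                 n_iter = 200, seed = 17)
  expect_identical(tab$k, tab2$k)
})

test_that("AMPLE maps are regional percentages with a strict 60% rule", {
  dm <- c(6, 6, 2)
  atlas <- array(1L, dm); atlas[4:6, , ] <- 2L
  tmap <- array(1, dm)
  tmap[1, 1, 1] <- 10; tmap[2, 1, 1] <- 6.5; tmap[3, 1, 1] <- 6.0
  tmap[4, 1, 1] <- 20; tmap[5, 1, 1] <- 13
  amp <- ample_map(tmap, atlas)
  expect_equal(amp[1, 1, 1], 100)
  expect_equal(amp[2, 1, 1], 65)
  expect_equal(amp[3, 1, 1], 60)
  expect_equal(amp[5, 1, 1], 65)
  mask <- array(TRUE, dm)
  act <- ample_threshold(tmap, atlas, mask, pct = 60)
  expect_true(act$active[2, 1, 1])
  expect_false(act$active[3, 1, 1])   # exactly 60 does not survive
  # scale invariance of the percentage-of-max rule
  expect_equal(ample_map(tmap * 7.3, atlas), amp)
  # a region with no positive t yields no activation
  tneg <- tmap; tneg[atlas == 2L] <- -1
  expect_warning(amp2 <- ample_map(tneg, atlas), "no positive")
  expect_true(all(amp2[atlas == 2L] == 0))
})

test_that("every method returns an empty map on a zero t-map and a mask subset otherwise", {
  cfg <- ideal_config(grid = c(14, 14, 10))
  mask <- brain_mask(cfg)
  atlas <- region_atlas(cfg)
  dm <- dim(mask)
  zero_stat <- fmritrt:::new_stat_map(
    list(task = array(0, dm)), list(task = array(0, dm)), 40,
    array(0, c(dm, 12)), mask, diag(c(4, 4, 4, 1)))
  for (m in c("Bon", "FDR", "AMPLE")) {
    act <- suppressWarnings(apply_threshold(zero_stat, m, atlas = atlas))
    expect_identical(sum(act$active), 0L, info = m)
  }
  act_c <- apply_threshold(zero_stat, "Clst", smoothness = 6, n_iter = 50,
                           seed = 2)
  expect_identical(sum(act_c$active), 0L)
})

test_that("Bonferroni-active voxels are a subset of BH-active voxels at equal alpha", {
  dm <- c(12, 12, 8)
  mask <- array(TRUE, dm)
  set.seed(19)
  tmap <- array(rnorm(prod(dm)), dm) + 2
  bon <- bonferroni_threshold(tmap, 50, mask, alpha = 0.01)
  bh <- fdr_threshold(tmap, 50, mask, q_thresh = 0.01)
  expect_true(all(bh$active[bon$active]))
})

test_that("all four methods recover a strong synthetic sphere", {
  fix <- ideal_session()
  cfg <- fix$cfg
  mc <- motion_correct_run(fix$s$bold, "NoMoCo")
  sm <- smooth_run(mc$bold, 6)
  stat <- fit_variant(sm, fix$s$paradigm, "Std")
  atlas <- region_atlas(cfg)
  smo <- estimate_smoothness(stat$residuals, stat$mask, 4)
  truth_vox <- round(fix$truths$run1[[1]]$center_mm / cfg$voxel_size_mm) + 1
  for (m in c("Bon", "FDR", "Clst", "AMPLE")) {
    act <- apply_threshold(stat, m, atlas = atlas, smoothness = smo,
                           n_iter = 100, seed = 3)
    expect_true(act$active[truth_vox[1], truth_vox[2], truth_vox[3]],
                info = m)
    expect_true(all(act$active <= stat$mask), info = m)
  }
})
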