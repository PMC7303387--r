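# helper: activation_map from a logical array + t values
make_act <- function(active, tmap = NULL, affine = diag(c(4, 4, 4, 1))) {
  if (is.null(tmap)) tmap <- array(as.numeric(active), dim(active))
  fmritrt:::new_activation_map(active, tmap, "Bon", list(),
                               array(TRUE, dim(active)), affine)
}

test_that("cluster extraction enforces the 12-voxel (768 ul) minimum", {
  dm <- c(12, 12, 8)
  a <- array(FALSE, dm)
  a[2:5, 2:4, 2] <- TRUE          # 12 voxels in one slab
  cl <- find_clusters(make_act(a), min_voxels = 12)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$volume_ul, 768)   # 12 x 4mm^3
  expect_identical(cl[[1]]$n_voxels, 12L)
  a2 <- a; a2[5, 4, 2] <- FALSE   # 11 voxels
  expect_length(find_clusters(make_act(a2), min_voxels = 12), 0)
})

test_that("corner-touching blobs are distinct clusters under 6-connectivity", {
  dm <- c(10, 10, 4)
  a <- array(FALSE, dm)
  a[2:3, 2:3, 2] <- TRUE
  a[4:5, 4:5, 2] <- TRUE          # touches only at the (3,3)-(4,4) corner
  cl <- find_clusters(make_act(a), min_voxels = 4)
  expect_length(cl, 2)
  # merge them with a face-sharing bridge
  a[4, 3, 2] <- TRUE
  cl2 <- find_clusters(make_act(a), min_voxels = 4)
  expect_length(cl2, 1)
})

test_that("the t-weighted center of mass weights positions by t", {
  aff <- diag(c(4, 4, 4, 1))
  idx <- rbind(c(1, 1, 1), c(2, 1, 1))   # x = 0 mm and 4 mm
  expect_equal(weighted_com(idx, c(1, 3), aff), c(3, 0, 0))
  # equal weights reduce to the geometric center
  expect_equal(weighted_com(idx, c(2, 2), aff), c(2, 0, 0))
  expect_error(weighted_com(idx, c(0, 0), aff))
})

test_that("ROI prevalence uses an inclusive at-least rule", {
  dm <- c(4, 4, 2)
  empty <- array(FALSE, dm)
  one <- empty; one[1, 1, 1] <- TRUE
  maps <- c(list(one), rep(list(empty), 9))
  roi <- build_roi_mask(maps, prevalence = 0.10)
  expect_true(roi[1, 1, 1])               # 1/10 = 10% >= 10%
  expect_identical(sum(roi), 1L)
  all_on <- array(TRUE, dm)
  expect_true(all(build_roi_mask(rep(list(all_on), 3), 1)))
  expect_error(build_roi_mask(list()))
})

test_that("ROI filtering keeps clusters by center of mass, not overlap", {
  dm <- c(12, 12, 6)
  aff <- diag(c(4, 4, 4, 1))
  a <- array(FALSE, dm); a[4:9, 5, 2] <- TRUE
  cl <- find_clusters(make_act(a), min_voxels = 4)
  expect_length(cl, 1)
  # ROI covering the CoM voxel
  roi_in <- array(FALSE, dm); roi_in[6:7, 5, 2] <- TRUE
  expect_length(filter_by_roi(cl, roi_in, aff), 1)
  # ROI overlapping the cluster tail but not the CoM
  roi_out <- array(FALSE, dm); roi_out[4, 5, 2] <- TRUE
  expect_length(filter_by_roi(cl, roi_out, aff), 0)
  expect_length(filter_by_roi(cl, array(FALSE, dm), aff), 0)
})

test_that("matching picks the closest retest cluster within 10 mm inclusive", {
  mk <- function(com, n = 20) structure(
    list(voxels = matrix(1, 1, 3), t_values = 1, n_voxels = n,
         volume_ul = n * 64, com_mm = com, linear_idx = seq_len(n)),
    class = "trt_cluster")
  t1 <- list(mk(c(0, 0, 0)))
  expect_length(match_clusters(t1, list(mk(c(10, 0, 0)))), 1)   # exactly 10
  expect_length(match_clusters(t1, list(mk(c(10.1, 0, 0)))), 0)
  picked <- match_clusters(t1, list(mk(c(7, 0, 0)), mk(c(4, 0, 0))))
  expect_equal(picked[[1]]$dcm_mm, 4)
  # many-to-one: two test clusters may share one retest cluster
  t2 <- list(mk(c(0, 0, 0)), mk(c(2, 0, 0)))
  m <- match_clusters(t2, list(mk(c(1, 0, 0))))
  expect_length(m, 2)
})

test_that("PDAV, DCM and DSC hit their ideals and textbook values", {
  expect_equal(pdav(500, 500), 0)
  expect_equal(pdav(100, 50), 200 / 3)
  expect_equal(pdav(100, 0), 200)
  expect_equal(pdav(3, 7), pdav(7, 3))
  expect_error(pdav(0, 0))

  expect_equal(dcm(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dcm(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(dcm(c(1, 1, 1), c(4, 5, 1)), dcm(c(4, 5, 1), c(1, 1, 1)))
  # triangle inequality
  a <- c(0, 0, 0); b <- c(5, 1, 2); cc <- c(2, 8, 3)
  expect_lte(dcm(a, cc), dcm(a, b) + dcm(b, cc))

  expect_equal(dsc(1:12, 1:12), 1)
  expect_equal(dsc(1:5, 6:10), 0)
  expect_equal(dsc(c(1, 2), c(2, 3)), 0.5)
  expect_equal(dsc(c(1, 2), c(2, 3)), dsc(c(2, 3), c(1, 2)))
  expect_error(dsc(integer(0), integer(0)))
})

test_that("matched pairs of identical activation maps give ideal metrics", {
  dm <- c(12, 12, 8)
  a <- array(FALSE, dm); a[3:6, 3:6, 3] <- TRUE
  t <- array(0, dm); t[a] <- runif(sum(a), 2, 8)
  cl1 <- find_clusters(make_act(a, t), min_voxels = 12)
  cl2 <- find_clusters(make_act(a, t), min_voxels = 12)
  pm <- pair_metrics(match_clusters(cl1, cl2))
  expect_identical(nrow(pm), 1L)
  expect_equal(pm$pdav_percent, 0)
  expect_equal(pm$dcm_mm, 0)
  expect_equal(pm$dsc, 1)
})
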