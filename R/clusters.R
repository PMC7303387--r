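# Cluster extraction, ROI prevalence masks, cross-session matching, and the
# three test-retest metrics (PDAV, DCM, DSC).

#' t-weighted center of mass of a voxel set
#'
#' @param idx N x 3 matrix of 1-based voxel indices.
#' @param t_values positive per-voxel t statistics (weights).
#' @param affine 4x4 voxel-to-mm affine.
#' @return 3-vector in mm.
#' @export
weighted_com <- function(idx, t_values, affine) {
  stopifnot(nrow(idx) == length(t_values))
  w <- sum(t_values)
  if (w <= 0) stop("non-positive total weight")
  mm <- voxel_to_mm(idx, affine)
  colSums(mm * t_values) / w
}

#' Extract activation clusters from a binary map
#'
#' Finds 6-face-connected components of the active voxels, discards those
#' smaller than `min_voxels` (default 12 voxels = 768 microliters at 4 mm
#' isotropic), and computes each survivor's volume and t-weighted center of
#' mass.
#'
#' @param act an `activation_map`.
#' @param min_voxels minimum cluster extent.
#' @return list of `trt_cluster` objects: each has `voxels` (N x 3 indices),
#'   `t_values`, `n_voxels`, `volume_ul`, `com_mm` and `linear_idx`.
#' @export
find_clusters <- function(act, min_voxels = 12) {
  stopifnot(inherits(act, "activation_map"))
  lab <- label_components_6(act$active)
  if (!any(lab > 0L)) return(list())
  affine <- act$affine %||% diag(4)
  voxel_vol_ul <- prod(abs(diag(affine)[1:3]))
  out <- list()
  sizes <- tabulate(lab[lab > 0L])
  dm <- dim(act$active)
  for (l in which(sizes >= min_voxels)) {
    lin <- which(lab == l)
    idx <- arrayInd(lin, dm)
    tv <- act$tmap[lin]
    out[[length(out) + 1]] <- structure(list(
      voxels = idx, t_values = tv, n_voxels = length(lin),
      volume_ul = length(lin) * voxel_vol_ul,
      com_mm = weighted_com(idx, tv, affine),
      linear_idx = lin
    ), class = "trt_cluster")
  }
  out
}

#' Build an ROI prevalence mask from many binary maps
#'
#' A voxel enters the ROI when it is active in at least `prevalence` of the
#' supplied maps (inclusive).
#'
#' @param maps list of logical 3D arrays (or `activation_map`s) on one grid.
#' @param prevalence required fraction (default 0.10).
#' @return logical 3D array.
#' @export
build_roi_mask <- function(maps, prevalence = 0.10) {
  stopifnot(length(maps) >= 1)
  arrs <- lapply(maps, function(m) if (inherits(m, "activation_map")) m$active else m)
  dm <- dim(arrs[[1]])
  count <- Reduce(`+`, lapply(arrs, function(a) array(as.numeric(a), dm)))
  count / length(arrs) >= prevalence
}

#' Keep clusters whose center of mass lies inside an ROI
#'
#' The mm center of mass is mapped to its containing voxel (floor after the
#' mm-to-voxel transform); the cluster is kept when that voxel is in the ROI.
#'
#' @param clusters list of `trt_cluster`s.
#' @param roi logical 3D ROI mask.
#' @param affine voxel-to-mm affine of the grid.
#' @return filtered list.
#' @export
filter_by_roi <- function(clusters, roi, affine) {
  keep <- vapply(clusters, function(cl) {
    v <- floor(mm_to_voxel(matrix(cl$com_mm, 1), affine))  # containing voxel
    v <- pmin(pmax(as.integer(v), 1L), dim(roi))
    isTRUE(roi[v[1], v[2], v[3]])
  }, logical(1))
  clusters[keep]
}

#' Match clusters across sessions by center-of-mass proximity
#'
#' For each test-session cluster independently, the closest retest-session
#' cluster with a center of mass at most `max_dist_mm` away (inclusive) is
#' selected; a retest cluster may be matched by more than one test cluster.
#'
#' @param test,retest lists of `trt_cluster`s from the same subject, run and
#'   pipeline.
#' @param max_dist_mm matching radius (default 10 mm).
#' @return list of pairs: each a list with `test`, `retest`, `dcm_mm`.
#' @export
match_clusters <- function(test, retest, max_dist_mm = 10) {
  if (length(test) == 0 || length(retest) == 0) return(list())
  pairs <- list()
  for (tc in test) {
    d <- vapply(retest, function(rc) dcm(tc$com_mm, rc$com_mm), numeric(1))
    j <- which.min(d)
    if (d[j] <= max_dist_mm) {
      pairs[[length(pairs) + 1]] <- list(test = tc, retest = retest[[j]],
                                         dcm_mm = d[j])
    }
  }
  pairs
}

#' Percent difference in activation volume
#'
#' `|V1 - V2| / ((V1 + V2) / 2) * 100`; 0 for identical volumes, 200 in the
#' limit where one volume vanishes.
#'
#' @param v1,v2 cluster volumes (any common unit).
#' @return percentage in [0, 200].
#' @export
pdav <- function(v1, v2) {
  stopifnot(v1 + v2 > 0, v1 >= 0, v2 >= 0)
  abs(v1 - v2) / ((v1 + v2) / 2) * 100
}

#' Distance between centers of mass
#'
#' Euclidean distance between two (t-weighted) centers of mass in mm.
#'
#' @param com1,com2 3-vectors in a common frame.
#' @return distance in mm.
#' @export
dcm <- function(com1, com2) {
  sqrt(sum((com1 - com2)^2))
}

#' Dice similarity coefficient of two voxel sets
#'
#' `2 |C1 and C2| / (|C1| + |C2|)`: 1 for identical sets, 0 for disjoint.
#'
#' @param c1,c2 vectors of linear voxel indices (or `trt_cluster`s) on one
#'   grid.
#' @return value in [0, 1].
#' @export
dsc <- function(c1, c2) {
  if (inherits(c1, "trt_cluster")) c1 <- c1$linear_idx
  if (inherits(c2, "trt_cluster")) c2 <- c2$linear_idx
  n1 <- length(unique(c1)); n2 <- length(unique(c2))
  stopifnot(n1 + n2 > 0)
  2 * length(intersect(c1, c2)) / (n1 + n2)
}

#' Test-retest metrics for a set of matched cluster pairs
#'
#' @param pairs output of [match_clusters()].
#' @return data.frame with one row per pair: `pdav_percent`, `dcm_mm`,
#'   `dsc`, and the two cluster volumes.
#' @export
pair_metrics <- function(pairs) {
  if (length(pairs) == 0) {
    return(data.frame(pdav_percent = numeric(0), dcm_mm = numeric(0),
                      dsc = numeric(0), v1_ul = numeric(0), v2_ul = numeric(0)))
  }
  do.call(rbind, lapply(pairs, function(p) data.frame(
    pdav_percent = pdav(p$test$volume_ul, p$retest$volume_ul),
    dcm_mm = p$dcm_mm,
    dsc = dsc(p$test, p$retest),
    v1_ul = p$test$volume_ul, v2_ul = p$retest$volume_ul
  )))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
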