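# Thresholding: conversion of t-statistic maps into binary activation maps
# by Bonferroni, FDR, Monte-Carlo cluster-extent and regional-percentage
# (AMPLE) rules. All tests are one-sided for positive t (task-positive
# activation).

#' One-sided p-value from a t statistic
#'
#' Upper-tail p under the Student t distribution (activation = positive t).
#'
#' @param t t statistic(s).
#' @param dof degrees of freedom.
#' @return p in (0, 1].
#' @export
p_from_t <- function(t, dof) {
  stopifnot(dof >= 1)
  stats::pt(t, df = dof, lower.tail = FALSE)
}

#' @noRd
new_activation_map <- function(active, tmap, method, params, mask, affine) {
  active[!mask] <- FALSE
  structure(list(active = active, tmap = tmap, method = method,
                 params = params, mask = mask, affine = affine),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("activation_map (%s): %d active voxels\n", x$method, sum(x$active)))
  invisible(x)
}

#' Bonferroni (familywise) threshold
#'
#' A voxel is active when its one-sided p-value times the number of mask
#' voxels is strictly below `alpha`.
#'
#' @param tmap 3D t map.
#' @param dof degrees of freedom.
#' @param mask logical 3D mask.
#' @param alpha corrected threshold (default .01).
#' @param affine voxel-to-mm affine of the grid (carried along for cluster
#'   geometry).
#' @return an `activation_map`.
#' @export
bonferroni_threshold <- function(tmap, dof, mask, alpha = 0.01,
                                 affine = diag(4)) {
  stopifnot(any(mask))
  n <- sum(mask)
  p <- p_from_t(tmap, dof)
  new_activation_map(p * n < alpha & mask, tmap, "Bon",
                     list(alpha = alpha, n_mask = n), mask, affine)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (a thin wrapper over `p.adjust`, kept as the
#' package's named operation).
#'
#' @param pvals vector of p-values in [0, 1].
#' @return adjusted q-values.
#' @export
fdr_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' False-discovery-rate threshold
#'
#' BH-adjusts the in-mask one-sided p-values and declares voxels with
#' q strictly below `q_thresh` active. The default 1e-5 is deliberately
#' stringent, matching the use of FDR as the most sensitive of the four
#' rules.
#'
#' @inheritParams bonferroni_threshold
#' @param q_thresh adjusted-p threshold (default 1e-5).
#' @return an `activation_map`.
#' @export
fdr_threshold <- function(tmap, dof, mask, q_thresh = 1e-5,
                          affine = diag(4)) {
  stopifnot(any(mask))
  p <- p_from_t(tmap[mask], dof)
  q <- fdr_adjust(p)
  active <- array(FALSE, dim(tmap))
  active[mask] <- q < q_thresh
  new_activation_map(active, tmap, "FDR", list(q_thresh = q_thresh), mask,
                     affine)
}

#' Estimate the spatial smoothness of the noise from residuals
#'
#' Gaussian-field estimator: residuals are variance-normalised per voxel,
#' and the variance of first spatial differences between neighbouring
#' in-mask voxels gives the lag-1 spatial correlation per axis, which under
#' a Gaussian autocorrelation model maps to a per-axis FWHM. Averaged over
#' residual volumes.
#'
#' @param residuals 4D residual array.
#' @param mask logical 3D mask.
#' @param voxel_size_mm voxel size (scalar or 3-vector).
#' @return object of class `smoothness_estimate`: list with `fwhm_mm`
#'   (per-axis) and `fwhm_geom_mm` (geometric mean over axes with positive
#'   estimates).
#' @export
estimate_smoothness <- function(residuals, mask, voxel_size_mm) {
  dm <- dim(residuals)
  stopifnot(length(dm) == 4, dm[4] >= 10, identical(dm[1:3], dim(mask)))
  vs <- rep(voxel_size_mm, length.out = 3)
  nt <- dm[4]
  R <- matrix(residuals, prod(dm[1:3]), nt)
  sdv <- sqrt(rowSums(R^2) / nt)
  ok <- mask & array(sdv > 0, dm[1:3])
  R <- R / ifelse(sdv > 0, sdv, 1)
  fwhm <- numeric(3)
  nxy <- dm[1] * dm[2]
  strides <- c(1, dm[1], nxy)
  idx_ok <- which(ok)
  for (ax in 1:3) {
    s <- strides[ax]
    # in-mask voxel pairs adjacent along this axis
    coord <- arrayInd(idx_ok, dm[1:3])[, ax]
    cand <- idx_ok[coord < dm[1:3][ax]]
    cand <- cand[ok[cand + s]]
    if (length(cand) < 2) stop("too few in-mask voxels along axis ", ax)
    d <- R[cand + s, , drop = FALSE] - R[cand, , drop = FALSE]
    vdiff <- mean(d^2)
    rho <- 1 - vdiff / 2
    # the field's ACF is the autocorrelation of the smoothing kernel, so the
    # ACF sigma is sqrt(2) times the kernel sigma; report the kernel FWHM
    fwhm[ax] <- if (rho <= 0) 0 else
      vs[ax] * 2 * sqrt(2 * log(2)) / sqrt(-4 * log(rho))
  }
  pos <- fwhm[fwhm > 0]
  geom <- if (length(pos)) exp(mean(log(pos))) else 0
  structure(list(fwhm_mm = fwhm, fwhm_geom_mm = geom),
            class = "smoothness_estimate")
}

#' Monte-Carlo minimum cluster size for a corrected alpha
#'
#' Simulates Gaussian null fields with the estimated smoothness inside the
#' mask, thresholds each at the one-sided voxelwise `voxel_p`, records the
#' largest 6-connected cluster, and returns, per alpha, the smallest cluster
#' size whose exceedance frequency is at or below alpha. Connectivity
#' matches the cluster extraction applied to real maps, so null and data are
#' treated identically. Deterministic given `seed` and `n_iter`.
#'
#' @param mask logical 3D mask.
#' @param smoothness a `smoothness_estimate` (its geometric-mean FWHM is
#'   used, as an isotropic Gaussian autocorrelation).
#' @param voxel_size_mm voxel size in mm.
#' @param voxel_p one-sided voxelwise threshold (default 1e-4).
#' @param alpha corrected alpha level(s) (default .01).
#' @param n_iter Monte-Carlo iterations (>= 1000 for pipeline use).
#' @param seed RNG seed.
#' @return object of class `cluster_size_table`: data.frame (`alpha`, `k`)
#'   plus the simulation settings as attributes.
#' @export
cluster_size_threshold <- function(mask, smoothness, voxel_size_mm,
                                   voxel_p = 1e-4, alpha = 0.01,
                                   n_iter = 1000, seed = 1L) {
  stopifnot(any(mask), n_iter >= 1)
  dm <- dim(mask)
  fwhm <- if (inherits(smoothness, "smoothness_estimate"))
    smoothness$fwhm_geom_mm else as.numeric(smoothness)
  zthr <- stats::qnorm(voxel_p, lower.tail = FALSE)
  set.seed(as.integer(seed))
  max_sizes <- integer(n_iter)
  inmask <- which(mask)
  for (it in seq_len(n_iter)) {
    f <- array(stats::rnorm(prod(dm)), dm)
    if (fwhm > 0) f <- gaussian_smooth_3d(f, fwhm, voxel_size_mm)
    v <- f[inmask]
    v <- (v - mean(v)) / stats::sd(v)
    supra <- array(FALSE, dm)
    supra[inmask[v > zthr]] <- TRUE
    if (!any(supra)) next
    lab <- label_components_6(supra)
    max_sizes[it] <- max(tabulate(lab[lab > 0L]))
  }
  k <- vapply(alpha, function(a) {
    for (s in 1:(max(max_sizes) + 1L)) {
      if (mean(max_sizes >= s) <= a) return(s)
    }
    max(max_sizes) + 1L
  }, integer(1))
  structure(data.frame(alpha = alpha, k = k),
            class = c("cluster_size_table", "data.frame"),
            voxel_p = voxel_p, n_iter = n_iter, seed = seed, fwhm_mm = fwhm)
}

#' Cluster-extent threshold
#'
#' Voxelwise one-sided p < `voxel_p`, then removal of 6-connected clusters
#' smaller than the Monte-Carlo minimum size `k` at the corrected alpha.
#'
#' @inheritParams bonferroni_threshold
#' @param voxel_p voxelwise threshold (default 1e-4).
#' @param table a `cluster_size_table` for this mask and smoothness (supply
#'   a cached one), or the arguments to build it via `smoothness`, `n_iter`,
#'   `seed`.
#' @param smoothness,n_iter,seed used only when `table` is NULL.
#' @param voxel_size_mm voxel size in mm.
#' @return an `activation_map`.
#' @export
cluster_threshold <- function(tmap, dof, mask, voxel_size_mm,
                              alpha = 0.01, voxel_p = 1e-4, table = NULL,
                              smoothness = NULL, n_iter = 1000, seed = 1L,
                              affine = diag(4)) {
  if (is.null(table)) {
    stopifnot(!is.null(smoothness))
    table <- cluster_size_threshold(mask, smoothness, voxel_size_mm,
                                    voxel_p = voxel_p, alpha = alpha,
                                    n_iter = n_iter, seed = seed)
  }
  k <- table$k[match(alpha, table$alpha)]
  stopifnot(!is.na(k))
  p <- p_from_t(tmap, dof)
  supra <- p < voxel_p & mask
  lab <- label_components_6(supra)
  if (any(supra)) {
    sizes <- tabulate(lab[lab > 0L])
    keep_lab <- which(sizes >= k)
    active <- array(lab %in% keep_lab, dim(tmap))
  } else {
    active <- supra
  }
  new_activation_map(active, tmap, "Clst",
                     list(alpha = alpha, voxel_p = voxel_p, k = k), mask,
                     affine)
}

#' Regional percentage-of-maximum (AMPLE) map
#'
#' Within each atlas region, t-statistics are divided by the regional
#' maximum t and expressed as a percentage. Regions whose maximum t is not
#' positive yield no activation (their values are set to 0, with a warning).
#' Negative percentages are floored at 0.
#'
#' @param tmap 3D t map.
#' @param atlas integer 3D region labels (0 = outside mask).
#' @return 3D array of percentages in [0, 100].
#' @export
ample_map <- function(tmap, atlas) {
  stopifnot(identical(dim(tmap), dim(atlas)))
  out <- array(0, dim(tmap))
  for (l in sort(unique(atlas[atlas > 0L]))) {
    sel <- atlas == l
    mx <- max(tmap[sel])
    if (mx <= 0) {
      warning("region ", l, " has no positive t; it yields no activation")
      next
    }
    out[sel] <- pmax(0, tmap[sel] / mx * 100)
  }
  out
}

#' AMPLE threshold
#'
#' Activation where the regional percentage-of-maximum strictly exceeds
#' `pct` (default 60).
#'
#' @inheritParams ample_map
#' @param mask logical 3D mask.
#' @param pct percentage threshold (strict >).
#' @return an `activation_map`.
#' @export
ample_threshold <- function(tmap, atlas, mask, pct = 60, affine = diag(4)) {
  amp <- ample_map(tmap, atlas)
  new_activation_map(amp > pct & mask, tmap, "AMPLE", list(pct = pct), mask,
                     affine)
}

#' Apply one thresholding method to a t map
#'
#' Dispatcher over the four rules. `Clst` needs a smoothness estimate (or a
#' cached `cluster_size_table`) and a seed; `AMPLE` needs a region atlas.
#'
#' @param stat a `stat_map`.
#' @param condition which condition's t map (defaults to the first).
#' @param method `"Bon"`, `"FDR"`, `"Clst"` or `"AMPLE"`.
#' @param atlas region atlas (AMPLE).
#' @param smoothness a `smoothness_estimate` (Clst).
#' @param cluster_table cached `cluster_size_table` (Clst).
#' @param n_iter,seed Monte-Carlo settings (Clst).
#' @param alpha corrected alpha for Bon and Clst.
#' @param fdr_q FDR adjusted-p threshold.
#' @param ample_pct AMPLE percentage threshold.
#' @return an `activation_map`.
#' @export
apply_threshold <- function(stat, method = c("Bon", "FDR", "Clst", "AMPLE"),
                            condition = NULL, atlas = NULL, smoothness = NULL,
                            cluster_table = NULL, n_iter = 1000, seed = 1L,
                            alpha = 0.01, fdr_q = 1e-5, ample_pct = 60) {
  method <- match.arg(method)
  stopifnot(inherits(stat, "stat_map"))
  if (is.null(condition)) condition <- names(stat$tmap)[1]
  tmap <- stat$tmap[[condition]]
  vs <- abs(diag(stat$affine)[1:3])
  out <- switch(method,
    Bon = bonferroni_threshold(tmap, stat$dof, stat$mask, alpha, stat$affine),
    FDR = fdr_threshold(tmap, stat$dof, stat$mask, fdr_q, stat$affine),
    Clst = {
      if (is.null(cluster_table) && is.null(smoothness)) {
        stop("Clst requires a smoothness estimate or a cluster_size_table")
      }
      cluster_threshold(tmap, stat$dof, stat$mask, vs, alpha = alpha,
                        voxel_p = 1e-4, table = cluster_table,
                        smoothness = smoothness, n_iter = n_iter, seed = seed,
                        affine = stat$affine)
    },
    AMPLE = {
      if (is.null(atlas)) stop("AMPLE requires a region atlas")
      ample_threshold(tmap, atlas, stat$mask, ample_pct, stat$affine)
    })
  out$params$condition <- condition
  out
}
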