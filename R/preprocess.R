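# Motion correction, framewise displacement and masked smoothing.

# Rotation matrix from (rx, ry, rz) in degrees, applied as Rz %*% Ry %*% Rx.
#' @noRd
rot3 <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Trilinear sampling of a 3D volume at fractional 1-based voxel coordinates
# (N x 3). Coordinates are clamped to the grid edge.
#' @noRd
interp_trilinear <- function(vol, vox) {
  dm <- dim(vol)
  x <- pmin(pmax(vox[, 1], 1), dm[1])
  y <- pmin(pmax(vox[, 2], 1), dm[2])
  z <- pmin(pmax(vox[, 3], 1), dm[3])
  x0 <- pmin(floor(x), dm[1] - 1); y0 <- pmin(floor(y), dm[2] - 1)
  z0 <- pmin(floor(z), dm[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  base <- (x0) + (y0 - 1) * nx + (z0 - 1) * nxy  # linear index of (x0,y0,z0)
  v <- vol
  dim(v) <- NULL
  c000 <- v[base];             c100 <- v[base + 1]
  c010 <- v[base + nx];        c110 <- v[base + nx + 1]
  c001 <- v[base + nxy];       c101 <- v[base + nxy + 1]
  c011 <- v[base + nx + nxy];  c111 <- v[base + nx + nxy + 1]
  (c000 * (1 - fx) + c100 * fx) * (1 - fy) * (1 - fz) +
    (c010 * (1 - fx) + c110 * fx) * fy * (1 - fz) +
    (c001 * (1 - fx) + c101 * fx) * (1 - fy) * fz +
    (c011 * (1 - fx) + c111 * fx) * fy * fz
}

#' Apply a rigid-body transform to a 3D volume
#'
#' Rotates (about the volume center, in mm) and translates the volume by the
#' six rigid parameters, resampling with trilinear interpolation.
#'
#' @param vol 3D array.
#' @param params length-6: rotations about x, y, z in degrees, then
#'   translations in mm.
#' @param affine 4x4 voxel-to-mm affine.
#' @return transformed 3D array.
#' @export
apply_rigid <- function(vol, params, affine) {
  dm <- dim(vol)
  mm <- voxel_to_mm(voxel_grid(dm), affine)
  ctr <- colMeans(mm[c(1, nrow(mm)), , drop = FALSE])
  R <- rot3(params[1:3])
  # output(p) = input(R^-1 (p - c - t) + c)
  q <- sweep(mm, 2, ctr + params[4:6]) %*% R + matrix(ctr, nrow(mm), 3, byrow = TRUE)
  vox <- mm_to_voxel(q, affine)
  array(interp_trilinear(vol, vox), dm)
}

#' Rigid-body registration of one volume to a reference
#'
#' Estimates the six rigid parameters (rotations in degrees, translations in
#' mm) that minimise the sum-of-squares intensity difference between the
#' transformed moving volume and the reference, by Nelder-Mead descent from
#' the identity, and returns the transformed volume. Intended for the small
#' within-run movements of fMRI time series; large displacements may need a
#' better starting point.
#'
#' @param moving,reference 3D arrays on the same grid.
#' @param affine 4x4 voxel-to-mm affine.
#' @param tol relative convergence tolerance.
#' @param init starting parameters (warm start, e.g. the previous volume's
#'   estimate when correcting a time series).
#' @param subsample integer stride for the voxels entering the cost
#'   function (the final resampling always uses the full grid).
#' @return list with `params` (length 6) and `resampled` (3D array);
#'   element `converged` reports optimizer status.
#' @export
rigid_register <- function(moving, reference, affine, tol = 1e-7,
                           init = rep(0, 6), subsample = 2L) {
  stopifnot(identical(dim(moving), dim(reference)))
  dm <- dim(moving)
  g <- voxel_grid(dm)
  if (subsample > 1L) {
    keep <- g[, 1] %% subsample == 1L & g[, 2] %% subsample == 1L &
      g[, 3] %% subsample == 1L
    g <- g[keep, , drop = FALSE]
  }
  mm <- voxel_to_mm(g, affine)
  full_mm <- voxel_to_mm(rbind(c(1, 1, 1), dm), affine)
  ctr <- colMeans(full_mm)
  ainv <- solve(affine)
  # the cost is evaluated on pre-smoothed copies: interpolation at fractional
  # offsets blurs the moving image, and on sharp data that energy loss can
  # masquerade as alignment; smoothing both volumes removes the bias. The
  # smoothing is edge-renormalized so it adds no grid-pinned boundary
  # structure that would anchor the fit to the identity. The final
  # resampling uses the raw moving volume.
  vs <- abs(diag(affine)[1:3])
  all_in <- array(TRUE, dm)
  mov_s <- smooth_in_mask(moving, 2 * vs[1], all_in, vs)
  ref_s <- smooth_in_mask(reference, 2 * vs[1], all_in, vs)
  ref <- ref_s[g]
  ssd <- function(p) {
    R <- rot3(p[1:3])
    q <- sweep(mm, 2, ctr + p[4:6]) %*% R + matrix(ctr, nrow(mm), 3, byrow = TRUE)
    vox <- cbind(q, 1) %*% t(ainv)
    d <- interp_trilinear(mov_s, vox[, 1:3, drop = FALSE] + 1) - ref
    sum(d * d)
  }
  if (ssd(rep(0, 6)) <= tol * sum(ref * ref)) {   # already aligned
    return(list(params = rep(0, 6), resampled = moving, converged = TRUE))
  }
  fit <- stats::optim(init, ssd, method = "Nelder-Mead",
                      control = list(reltol = tol, maxit = 400))
  # one restart from the found optimum sharpens the collapsed simplex
  fit2 <- stats::optim(fit$par, ssd, method = "Nelder-Mead",
                       control = list(reltol = tol, maxit = 200))
  improved <- fit2$value < fit$value * (1 - 1e-3)
  if (fit2$value < fit$value) fit <- fit2
  converged <- fit$convergence == 0 || !improved
  if (!converged) {
    warning("rigid_register: optimizer did not fully converge; returning best found")
  }
  list(params = fit$par, resampled = apply_rigid(moving, fit$par, affine),
       converged = converged)
}

#' Motion-correct a BOLD run
#'
#' `"NoMoCo"` leaves the data untouched and reports all-zero motion
#' parameters; `"Rigid3D"` registers every volume to the first volume with
#' [rigid_register()]. In both arms the first volume is then dropped.
#'
#' @param run a `bold4d`.
#' @param method `"NoMoCo"` or `"Rigid3D"`.
#' @return list with `bold` (first volume removed), `params` (n-1 x 6 rigid
#'   parameters of the retained volumes) and `method`.
#' @export
motion_correct_run <- function(run, method = c("NoMoCo", "Rigid3D")) {
  method <- match.arg(method)
  stopifnot(inherits(run, "bold4d"), dim(run$data)[4] >= 2)
  nt <- dim(run$data)[4]
  params <- matrix(0, nt, 6,
                   dimnames = list(NULL, c("rx_deg", "ry_deg", "rz_deg",
                                           "tx_mm", "ty_mm", "tz_mm")))
  data <- run$data
  if (method == "Rigid3D") {
    ref <- run$data[, , , 1]
    prev <- rep(0, 6)
    for (t in 2:nt) {
      reg <- rigid_register(run$data[, , , t], ref, run$affine, init = prev)
      params[t, ] <- reg$params
      prev <- reg$params
      data[, , , t] <- reg$resampled
    }
  }
  keep <- 2:nt
  list(bold = bold4d(data[, , , keep, drop = FALSE], run$affine,
                     run$tr_seconds, run$mask),
       params = params[keep, , drop = FALSE], method = method)
}

#' Estimate motion parameters only (no resampling)
#'
#' Runs the rigid registration of every volume to the first and returns the
#' parameter track; used when a regression variant needs framewise
#' displacement or motion covariates in an arm whose data were not
#' resampled.
#'
#' @inheritParams motion_correct_run
#' @return (n-1) x 6 matrix for the retained volumes (first volume dropped).
#' @export
estimate_motion_params <- function(run) {
  motion_correct_run(run, "Rigid3D")$params
}

#' Framewise displacement from rigid motion parameters
#'
#' Power-style FD: the sum of absolute backward differences of the six
#' parameters, with rotations converted from degrees to arc length on a
#' 50 mm sphere. The first entry is 0.
#'
#' @param params n x 6 matrix (rx, ry, rz degrees; tx, ty, tz mm).
#' @param radius_mm head-sphere radius for the rotation arc length.
#' @return non-negative vector of length n.
#' @export
framewise_displacement <- function(params, radius_mm = 50) {
  stopifnot(ncol(params) == 6)
  if (nrow(params) == 1) return(0)
  d <- abs(diff(params))
  d[, 1:3] <- d[, 1:3] * pi / 180 * radius_mm
  c(0, rowSums(d))
}

#' Gaussian smoothing restricted to a brain mask
#'
#' Smooths only within the mask with renormalisation —
#' `smooth(data * mask) / smooth(mask)` — so intensity never bleeds across
#' the mask edge and a constant field stays exactly constant. Voxels outside
#' the mask are set to zero. An FWHM of 0 is the identity inside the mask.
#'
#' @param data 3D or 4D array.
#' @param fwhm_mm smoothing kernel FWHM in mm (0 for none).
#' @param mask logical 3D array.
#' @param voxel_size_mm voxel size (scalar or per-axis).
#' @return array of the same shape.
#' @export
smooth_in_mask <- function(data, fwhm_mm, mask, voxel_size_mm) {
  stopifnot(any(mask))
  dm <- dim(data)
  m <- array(as.numeric(mask), dim(mask))
  smooth_one <- function(vol) {
    if (fwhm_mm <= 0) return(vol * m)
    num <- gaussian_smooth_3d(vol * m, fwhm_mm, voxel_size_mm)
    den <- gaussian_smooth_3d(m, fwhm_mm, voxel_size_mm)
    out <- array(0, dim(vol))
    inm <- mask
    out[inm] <- num[inm] / den[inm]
    out
  }
  if (length(dm) == 3) return(smooth_one(data))
  out <- data
  for (t in seq_len(dm[4])) out[, , , t] <- smooth_one(data[, , , t])
  out
}

#' Masked smoothing of a BOLD run
#'
#' @param run a `bold4d`.
#' @param fwhm_mm kernel FWHM in mm.
#' @return a `bold4d` with each volume smoothed within the run's mask.
#' @export
smooth_run <- function(run, fwhm_mm) {
  stopifnot(inherits(run, "bold4d"))
  vs <- abs(diag(run$affine)[1:3])
  bold4d(smooth_in_mask(run$data, fwhm_mm, run$mask, vs),
         run$affine, run$tr_seconds, run$mask)
}
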