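# Internal array / geometry helpers shared across stages.

#' @keywords internal
#' @noRd
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Deterministic sub-seed derivation: mixes a base seed with small integer tags
# (subject, session, run index ...) into a 31-bit seed.
#' @noRd
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 31 + (as.numeric(t) %% 2147483647)) %% 2147483647
  as.integer(h %% 2147483629L + 1L)
}

# 1D Gaussian kernel (normalised to sum 1), truncated at 4 sigma.
#' @noRd
gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve a 3D array along one axis with a 1D kernel (zero-padded edges).
# Implemented as a dense band-matrix product on the permuted array; grids are
# small (tens of voxels per axis) so this is fast and exact.
#' @noRd
convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- kernel[ok]
  }
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dim(x) <- c(n, prod(d[-axis]))
  y <- K %*% x
  dim(y) <- d[perm]
  aperm(y, order(perm))
}

# Plain (unmasked) separable Gaussian smoothing of a 3D array.
#' @noRd
gaussian_smooth_3d <- function(arr, fwhm_mm, voxel_size_mm) {
  if (all(fwhm_mm <= 0)) return(arr)
  fw <- rep(fwhm_mm, length.out = 3)
  vs <- rep(voxel_size_mm, length.out = 3)
  for (ax in 1:3) {
    sig <- fwhm_to_sigma(fw[ax]) / vs[ax]
    arr <- convolve_axis(arr, gauss_kernel_1d(sig), ax)
  }
  arr
}

# Voxel index grid (1-based i,j,k) for a given 3D dim, as an N x 3 matrix.
#' @noRd
voxel_grid <- function(dm) {
  cbind(
    rep(seq_len(dm[1]), times = dm[2] * dm[3]),
    rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]),
    rep(seq_len(dm[3]), each = dm[1] * dm[2])
  )
}

# Apply a 4x4 voxel->mm affine to 1-based voxel indices (N x 3) -> N x 3 mm.
# The affine maps 0-based voxel coordinates, the NIfTI convention.
#' @noRd
voxel_to_mm <- function(ijk, affine) {
  v0 <- cbind(ijk - 1, 1)
  mm <- v0 %*% t(affine)
  mm[, 1:3, drop = FALSE]
}

#' @noRd
mm_to_voxel <- function(mm, affine) {
  v <- cbind(mm, 1) %*% t(solve(affine))
  v[, 1:3, drop = FALSE] + 1
}

# Connected components of a logical 3D array under 6-face connectivity.
# Returns an integer label array (0 = background). Visits only foreground
# voxels, so cost scales with the activation size, not the grid.
#' @noRd
label_components_6 <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nxy <- dm[1] * dm[2]
  cur <- 0L
  stack <- integer(0)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack) > 0L) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      k <- (v - 1L) %/% nxy
      rem <- (v - 1L) %% nxy
      j <- rem %/% dm[1]
      i <- rem %% dm[1]
      nb <- integer(0)
      if (i > 0L) nb <- c(nb, v - 1L)
      if (i < dm[1] - 1L) nb <- c(nb, v + 1L)
      if (j > 0L) nb <- c(nb, v - dm[1])
      if (j < dm[2] - 1L) nb <- c(nb, v + dm[1])
      if (k > 0L) nb <- c(nb, v - nxy)
      if (k < dm[3] - 1L) nb <- c(nb, v + nxy)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        stack <- c(stack, nb)
      }
    }
  }
  lab
}
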