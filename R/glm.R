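# Task regression: design construction and the five fitting variants.

# Legendre polynomials P0..Pk evaluated on [-1, 1] over n points.
#' @noRd
legendre_basis <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  B <- matrix(1, n, order + 1)
  if (order >= 1) B[, 2] <- x
  if (order >= 2) for (k in 2:order) {
    B[, k + 1] <- ((2 * k - 1) * x * B[, k] - (k - 1) * B[, k - 1]) / k
  }
  colnames(B) <- paste0("poly", 0:order)
  B
}

#' Censor flags from framewise displacement
#'
#' A volume is censored when its FD strictly exceeds the threshold.
#'
#' @param fd framewise-displacement series.
#' @param threshold FD threshold in mm (0.2 strict, 0.5 lenient).
#' @return logical vector, `TRUE` = censor.
#' @export
censor_flags <- function(fd, threshold) {
  stopifnot(threshold > 0)
  fd > threshold
}

#' Build the regression design for one run
#'
#' Columns are the task regressor(s) from [condition_regressor()], a
#' Legendre polynomial baseline whose order follows the run length rule
#' (order 1 below 150 volumes, order 2 at 150 or more, counted on the
#' as-acquired run length), and, for the `MPC` variant, the six rigid motion
#' parameters as nuisance covariates. `Cen2` / `Cen5` flag volumes with
#' FD > 0.2 / 0.5 mm for censoring. The first acquired volume is assumed
#' dropped, so the design covers volumes 2..n.
#'
#' @param paradigm a `task_paradigm`.
#' @param variant one of `"Std"`, `"REML"`, `"Cen2"`, `"Cen5"`, `"MPC"`.
#' @param motion (n-1) x 6 motion parameters (required for `MPC`).
#' @param fd framewise displacement of the retained volumes (required for
#'   `Cen2` / `Cen5`).
#' @return object of class `trt_design`: list with `X` (rows = retained
#'   volumes), `task_cols` (named indices of the condition regressors),
#'   `censor` (logical per row) and `variant`.
#' @export
build_design <- function(paradigm, variant = c("Std", "REML", "Cen2", "Cen5", "MPC"),
                         motion = NULL, fd = NULL) {
  variant <- match.arg(variant)
  n_full <- paradigm$n_volumes
  n <- n_full - 1L
  order <- if (n_full < 150) 1L else 2L
  conds <- paradigm$condition_labels
  task <- sapply(conds, function(cc) condition_regressor(paradigm, cc)[-1])
  task <- matrix(task, n, length(conds), dimnames = list(NULL, conds))
  X <- cbind(task, legendre_basis(n, order))
  censor <- rep(FALSE, n)
  if (variant == "MPC") {
    if (is.null(motion)) stop("MPC variant requires motion parameters")
    stopifnot(nrow(motion) == n, ncol(motion) == 6)
    mp <- scale(motion, scale = FALSE)   # center so baseline stays interpretable
    colnames(mp) <- paste0("motion", 1:6)
    X <- cbind(X, mp)
  }
  if (variant %in% c("Cen2", "Cen5")) {
    if (is.null(fd)) stop(sprintf("%s variant requires a framewise-displacement series", variant))
    stopifnot(length(fd) == n)
    censor <- censor_flags(fd, if (variant == "Cen2") 0.2 else 0.5)
  }
  if (qr(X[!censor, , drop = FALSE])$rank < ncol(X)) {
    stop("design matrix is rank deficient after censoring")
  }
  structure(list(X = X, task_cols = stats::setNames(seq_along(conds), conds),
                 censor = censor, variant = variant,
                 poly_order = order), class = "trt_design")
}

#' @noRd
new_stat_map <- function(tmaps, betas, dof, resid4d, mask, affine) {
  structure(list(tmap = tmaps, betas = betas, dof = dof,
                 residuals = resid4d, mask = mask, affine = affine),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map: conditions %s, dof = %d, grid %s\n",
              paste(names(x$tmap), collapse = "/"), x$dof,
              paste(dim(x$tmap[[1]]), collapse = "x")))
  invisible(x)
}

# Shared least-squares core: X (kept rows) against Y (kept rows x voxels).
# Returns per-condition beta and t over the in-mask voxels.
#' @noRd
ols_core <- function(X, Y, task_cols) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  dof <- nrow(X) - qrX$rank
  if (dof <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / dof
  XtXinv <- chol2inv(chol(crossprod(X)))
  se_fac <- sqrt(diag(XtXinv)[task_cols])
  names(se_fac) <- names(task_cols)
  list(beta = beta, res = res, dof = dof, sigma2 = sigma2, se_fac = se_fac)
}

#' Ordinary least-squares fit of a run (the `Std` variant)
#'
#' Fits every in-mask voxel's time series on the design by OLS after
#' deleting censored rows, and returns per-condition t-statistic maps plus
#' the residuals needed for smoothness estimation.
#'
#' @param run a `bold4d` (first volume already removed).
#' @param design a `trt_design` from [build_design()].
#' @return object of class `stat_map`: named lists `tmap` and `betas`
#'   (3D arrays per condition, 0 outside the mask), `dof`, `residuals`
#'   (4D over the uncensored volumes), `mask`, `affine`.
#' @export
fit_ols <- function(run, design) {
  stopifnot(inherits(run, "bold4d"), inherits(design, "trt_design"))
  dm <- dim(run$data)
  stopifnot(dm[4] == nrow(design$X))
  keep <- !design$censor
  vox <- which(run$mask)
  Y <- matrix(run$data, prod(dm[1:3]), dm[4])[vox, , drop = FALSE]
  Y <- t(Y)[keep, , drop = FALSE]
  X <- design$X[keep, , drop = FALSE]
  fit <- ols_core(X, Y, design$task_cols)
  pack <- function(v) { a <- array(0, dm[1:3]); a[vox] <- v; a }
  tmaps <- betas <- list()
  for (cc in names(design$task_cols)) {
    j <- design$task_cols[[cc]]
    b <- fit$beta[j, ]
    se <- sqrt(fit$sigma2) * fit$se_fac[[cc]]
    tv <- ifelse(se > 0, b / se, 0)
    betas[[cc]] <- pack(b)
    tmaps[[cc]] <- pack(tv)
  }
  resid4d <- array(0, c(dm[1:3], sum(keep)))
  rm <- matrix(0, prod(dm[1:3]), sum(keep))
  rm[vox, ] <- t(fit$res)
  resid4d <- array(rm, c(dm[1:3], sum(keep)))
  new_stat_map(tmaps, betas, fit$dof, resid4d, run$mask, run$affine)
}

#' AR(1)-prewhitened fit of a run (the `REML` variant)
#'
#' Estimates a lag-1 autoregressive coefficient per voxel from the OLS
#' residuals (Cochrane-Orcutt style), prewhitens data and design with the
#' exact AR(1) square-root transform, and refits by OLS. Voxels are grouped
#' into rho bins of 0.01 so each whitening is applied once per bin. Degrees
#' of freedom follow the design rank only. Estimates with |rho| >= 1 are
#' clipped to 0.99 with a warning.
#'
#' @inheritParams fit_ols
#' @param rho_pool_fwhm FWHM (mm) of the in-mask spatial pooling applied to
#'   the voxelwise rho estimates before prewhitening.
#' @return a `stat_map`; the pooled per-voxel rho estimates are attached as
#'   attribute `rho` (3D array).
#' @export
fit_reml_ar1 <- function(run, design, rho_pool_fwhm = 12) {
  stopifnot(inherits(run, "bold4d"), inherits(design, "trt_design"))
  dm <- dim(run$data)
  keep <- !design$censor
  vox <- which(run$mask)
  Y <- matrix(run$data, prod(dm[1:3]), dm[4])[vox, , drop = FALSE]
  Y <- t(Y)[keep, , drop = FALSE]
  X <- design$X[keep, , drop = FALSE]
  n <- nrow(Y)

  ols <- ols_core(X, Y, design$task_cols)
  r <- ols$res
  num <- colSums(r[-1, , drop = FALSE] * r[-n, , drop = FALSE])
  den <- colSums(r^2)
  rho <- ifelse(den > 0, num / den, 0)
  if (any(abs(rho) >= 1)) {
    warning("AR(1) estimates with |rho| >= 1 clipped to 0.99")
    rho[rho >= 1] <- 0.99
    rho[rho <= -1] <- -0.99
  }
  # regularise the voxelwise estimates by spatial pooling within the mask,
  # as prewhitening tools do; raw lag-1 estimates are too noisy at run length
  rho_arr <- array(0, dm[1:3])
  rho_arr[vox] <- rho
  vs3 <- abs(diag(run$affine)[1:3])
  rho_arr <- smooth_in_mask(rho_arr, rho_pool_fwhm, run$mask, vs3)
  rho <- pmax(pmin(rho_arr[vox], 0.99), -0.99)
  rho_bin <- round(rho, 2)

  pack <- function(v) { a <- array(0, dm[1:3]); a[vox] <- v; a }
  nb <- length(vox)
  bmat <- matrix(0, length(design$task_cols), nb)
  tmat <- matrix(0, length(design$task_cols), nb)
  resw <- matrix(0, n, nb)
  dof <- NULL
  for (rb in unique(rho_bin)) {
    sel <- which(rho_bin == rb)
    # exact AR(1) whitening: first row * sqrt(1-rho^2), then y_t - rho*y_{t-1}
    W <- function(M) {
      Mw <- M
      Mw[1, ] <- M[1, ] * sqrt(1 - rb^2)
      Mw[-1, ] <- M[-1, , drop = FALSE] - rb * M[-n, , drop = FALSE]
      Mw
    }
    fit <- ols_core(W(X), W(Y[, sel, drop = FALSE]), design$task_cols)
    dof <- fit$dof
    for (ci in seq_along(design$task_cols)) {
      j <- design$task_cols[[ci]]
      b <- fit$beta[j, ]
      se <- sqrt(fit$sigma2) * fit$se_fac[[ci]]
      bmat[ci, sel] <- b
      tmat[ci, sel] <- ifelse(se > 0, b / se, 0)
    }
    resw[, sel] <- fit$res
  }
  tmaps <- betas <- list()
  for (ci in seq_along(design$task_cols)) {
    cc <- names(design$task_cols)[ci]
    betas[[cc]] <- pack(bmat[ci, ])
    tmaps[[cc]] <- pack(tmat[ci, ])
  }
  rm <- matrix(0, prod(dm[1:3]), n)
  rm[vox, ] <- t(resw)
  out <- new_stat_map(tmaps, betas, dof, array(rm, c(dm[1:3], n)),
                      run$mask, run$affine)
  attr(out, "rho") <- pack(rho)
  out
}

#' Fit one regression variant
#'
#' Dispatcher over the five variants: `Std` (plain OLS), `REML`
#' (AR(1)-prewhitened), `Cen2` / `Cen5` (OLS with FD-censored volumes
#' deleted) and `MPC` (OLS with the six motion parameters as covariates).
#'
#' @param run a `bold4d` (first volume removed).
#' @param paradigm the run's `task_paradigm`.
#' @param variant regression variant name.
#' @param motion,fd motion parameters / FD series where the variant needs them.
#' @return a `stat_map`.
#' @export
fit_variant <- function(run, paradigm, variant, motion = NULL, fd = NULL) {
  design <- build_design(paradigm, variant, motion = motion, fd = fd)
  if (variant == "REML") fit_reml_ar1(run, design) else fit_ols(run, design)
}
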