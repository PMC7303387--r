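#' Construct a 4D BOLD container
#'
#' @param data 4D array (x, y, z, time).
#' @param affine 4x4 voxel-to-mm matrix (0-based voxel convention).
#' @param tr_seconds repetition time.
#' @param mask logical 3D brain mask on the same grid.
#' @return object of class `bold4d`.
#' @export
bold4d <- function(data, affine, tr_seconds, mask) {
  stopifnot(length(dim(data)) == 4, identical(dim(data)[1:3], dim(mask)),
            identical(dim(affine), c(4L, 4L)), tr_seconds > 0)
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds,
                 mask = mask), class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold4d: %dx%dx%d grid, %d volumes, TR %.1f s, %d mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr_seconds, sum(x$mask)))
  invisible(x)
}

#' @export
dim.bold4d <- function(x) dim(x$data)

#' Ground-truth activation cluster
#'
#' A spherical activation of known location, size and percent-signal-change
#' amplitude, driven by one task condition. A raised-cosine roll-off of one
#' voxel width at the sphere edge gives clusters stable but non-trivial
#' boundaries.
#'
#' @param center_mm 3-vector, mm coordinates.
#' @param radius_mm sphere radius, mm.
#' @param amplitude percent signal change at the sphere core.
#' @param condition_label the task condition driving the activation.
#' @export
ground_truth_cluster <- function(center_mm, radius_mm, amplitude, condition_label) {
  stopifnot(length(center_mm) == 3, radius_mm > 0)
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 amplitude = amplitude, condition_label = condition_label),
            class = "ground_truth_cluster")
}

#' Simulation configuration
#'
#' Parameters of the synthetic two-session cohort. Defaults mirror the
#' acquisition the package emulates (4 mm isotropic voxels) on a reduced
#' 32 x 32 x 24 grid, with an AR(1) noise coefficient, spatially smooth
#' noise, and small between-session center-of-mass and amplitude jitter.
#'
#' @param n_subjects number of subjects (two sessions each).
#' @param grid_shape 3 integers, voxel grid.
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param noise_sd additive noise SD in signal units (baseline is 100, so
#'   1.0 means 1% of baseline).
#' @param ar1_rho lag-1 temporal autocorrelation of the noise, in [0, 1).
#' @param noise_fwhm_mm spatial smoothness (FWHM) of the noise field.
#' @param session_com_jitter_sd_mm SD of the session-2 displacement of each
#'   true activation center, per axis.
#' @param session_amplitude_jitter_sd SD of the additive session-2 amplitude
#'   perturbation (percent-signal-change units).
#' @param motion_profile `"none"`, or a function(n_volumes) returning an
#'   n x 6 matrix of per-volume rigid parameters (rx, ry, rz in degrees,
#'   tx, ty, tz in mm) applied to the simulated volumes.
#' @param seed base random seed; all session-level seeds derive from it.
#' @export
simulation_config <- function(n_subjects = 10, grid_shape = c(32, 32, 24),
                              voxel_size_mm = 4, noise_sd = 1,
                              ar1_rho = 0.3, noise_fwhm_mm = 6,
                              session_com_jitter_sd_mm = 2,
                              session_amplitude_jitter_sd = 0.2,
                              motion_profile = "none", seed = 1L) {
  stopifnot(n_subjects >= 1, length(grid_shape) == 3, all(grid_shape >= 4),
            voxel_size_mm > 0, noise_sd >= 0, ar1_rho >= 0, ar1_rho < 1,
            noise_fwhm_mm >= 0, session_com_jitter_sd_mm >= 0,
            session_amplitude_jitter_sd >= 0)
  structure(list(n_subjects = n_subjects, grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, noise_sd = noise_sd,
                 ar1_rho = ar1_rho, noise_fwhm_mm = noise_fwhm_mm,
                 session_com_jitter_sd_mm = session_com_jitter_sd_mm,
                 session_amplitude_jitter_sd = session_amplitude_jitter_sd,
                 motion_profile = motion_profile, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @noRd
sim_affine <- function(config) {
  a <- diag(c(rep(config$voxel_size_mm, 3), 1))
  a
}

#' Analytic ellipsoid brain mask for a simulation grid
#'
#' @param config a `simulation_config`.
#' @return logical 3D array.
#' @export
brain_mask <- function(config) {
  dm <- config$grid_shape
  g <- voxel_grid(dm)
  c0 <- (dm + 1) / 2
  semi <- (dm / 2 - 0.5)
  r2 <- ((g[, 1] - c0[1]) / semi[1])^2 + ((g[, 2] - c0[2]) / semi[2])^2 +
    ((g[, 3] - c0[3]) / semi[3])^2
  array(r2 <= 1, dm)
}

#' Octant-sector region atlas on the synthetic brain mask
#'
#' Partitions the mask into five sectors standing in for the frontal,
#' occipital, parietal and temporal lobes plus "other": the inferior half of
#' the mask is "other", the superior half is split into four x/y quadrants.
#' Used by the regional-percentage (AMPLE) threshold.
#'
#' @param config a `simulation_config`.
#' @return integer 3D array with levels 1..5 inside the mask, 0 outside;
#'   attribute `labels` names the sectors.
#' @export
region_atlas <- function(config) {
  dm <- config$grid_shape
  mask <- brain_mask(config)
  g <- voxel_grid(dm)
  c0 <- (dm + 1) / 2
  lab <- integer(prod(dm))
  sup <- g[, 3] > c0[3]
  lab[!sup] <- 5L                                    # other
  lab[sup & g[, 1] <= c0[1] & g[, 2] <= c0[2]] <- 1L # frontal
  lab[sup & g[, 1] > c0[1] & g[, 2] <= c0[2]] <- 2L  # occipital
  lab[sup & g[, 1] <= c0[1] & g[, 2] > c0[2]] <- 3L  # parietal
  lab[sup & g[, 1] > c0[1] & g[, 2] > c0[2]] <- 4L   # temporal
  atlas <- array(lab, dm)
  atlas[!mask] <- 0L
  attr(atlas, "labels") <- c("frontal", "occipital", "parietal", "temporal", "other")
  atlas
}

#' Default ground-truth activations for each run
#'
#' One sphere per task condition, placed at fixed in-mask locations, with
#' amplitudes of 2-3 percent signal change typical of strong block-design
#' activation at 1.5 T.
#'
#' @param config a `simulation_config`.
#' @param runs which runs to cover.
#' @return named list (per run) of lists of [ground_truth_cluster()]s.
#' @export
default_truths <- function(config, runs = paste0("run", 1:5)) {
  vs <- config$voxel_size_mm
  dm <- config$grid_shape
  ctr <- (dm - 1) / 2 * vs       # mm center of the grid
  off <- function(dx, dy, dz) ctr + c(dx, dy, dz) * vs
  sph <- function(center, cond, amp = 2.5, r = 2.2 * vs)
    ground_truth_cluster(center, r, amp, cond)
  all <- list(
    run1 = list(sph(off(-3, -2, 2), "task"), sph(off(3, 2, 2), "task", amp = 2)),
    run2 = list(sph(off(-3, 2, 2), "task"), sph(off(3, -2, 2), "task", amp = 2)),
    run3 = list(sph(off(-3, -2, 2), "task"), sph(off(3, 2, 2), "task", amp = 2)),
    run4 = list(sph(off(-3, 0, 3), "finger"), sph(off(0, -3, 3), "foot"),
                sph(off(3, 0, 3), "lips")),
    run5 = list(sph(off(-3, 3, 2), "landmark"), sph(off(3, -3, 2), "detection"))
  )
  all[runs]
}

# Spherical weight field with one-voxel raised-cosine edge roll-off;
# exactly zero beyond radius_mm.
#' @noRd
sphere_weights <- function(truth, config, affine) {
  dm <- config$grid_shape
  mm <- voxel_to_mm(voxel_grid(dm), affine)
  r <- sqrt(rowSums(sweep(mm, 2, truth$center_mm)^2))
  w <- numeric(length(r))
  edge <- config$voxel_size_mm
  core <- max(truth$radius_mm - edge, 0)
  w[r <= core] <- 1
  roll <- r > core & r <= truth$radius_mm
  w[roll] <- 0.5 * (1 + cos(pi * (r[roll] - core) / (truth$radius_mm - core)))
  array(w, dm)
}

# AR(1) filter along time for a (voxels x T) matrix, then rescale the whole
# noise array so its pooled SD equals target_sd.
#' @noRd
ar1_filter_scale <- function(noise, rho, target_sd) {
  if (rho > 0) {
    for (t in 2:ncol(noise)) noise[, t] <- rho * noise[, t - 1] + noise[, t]
  }
  s <- stats::sd(as.vector(noise))
  if (s > 0) noise <- noise * (target_sd / s)
  noise
}

# Per-subject anatomical baseline: a smooth-edged head (the ellipsoid mask
# blurred by 1.5 voxels) at intensity 100, overlaid with a fixed smooth
# intensity texture (SD 10) standing in for tissue contrast. Identical
# across sessions, runs and volumes of a subject, so motion estimation has
# the same anatomical structure to lock onto as real EPI data.
#' @noRd
anatomy_volume <- function(config, subject) {
  dm <- config$grid_shape
  vs <- config$voxel_size_mm
  mask <- brain_mask(config)
  set.seed(derive_seed(config$seed, subject, 777L))
  head <- gaussian_smooth_3d(array(as.numeric(mask), dm), 1.5 * vs, vs)
  tex <- gaussian_smooth_3d(array(stats::rnorm(prod(dm)), dm), 3 * vs, vs)
  tex <- tex / stats::sd(tex)
  (100 + 10 * tex) * head
}

#' Simulate one run of one session
#'
#' A smooth-edged head-shaped baseline (intensity 100 with a fixed
#' per-subject texture) plus, for each ground-truth cluster, a spherical activation
#' whose time course is `amplitude x condition_regressor`. For session 2 the
#' cluster centers are jittered by `session_com_jitter_sd_mm` and amplitudes
#' by `session_amplitude_jitter_sd`. Additive noise is white Gaussian,
#' spatially smoothed to `noise_fwhm_mm`, AR(1)-filtered in time
#' (`ar1_rho`), and rescaled to pooled SD `noise_sd`. An optional rigid
#' motion schedule is applied per volume by resampling. Fully reproducible
#' from the config seed and the (subject, session, run) tags.
#'
#' @param config a `simulation_config`.
#' @param subject,session integer tags (session is 1 or 2).
#' @param run run id, `"run1" ... "run5"`.
#' @param truths list of [ground_truth_cluster()]s for this run.
#' @return list with `bold` (a `bold4d`), `motion` (n x 6 true rigid
#'   parameters), `truths` (the jittered ground truth actually injected) and
#'   `paradigm`.
#' @export
simulate_session <- function(config, subject, session, run, truths) {
  stopifnot(inherits(config, "simulation_config"), session %in% 1:2)
  par <- build_paradigm(run)
  dm <- config$grid_shape
  nt <- par$n_volumes
  affine <- sim_affine(config)
  mask <- brain_mask(config)
  run_i <- as.integer(sub("run", "", run))

  anat <- anatomy_volume(config, subject)
  set.seed(derive_seed(config$seed, subject, session, run_i))

  # session-2 jitter of the ground truth
  used <- lapply(truths, function(tr) {
    if (session == 2) {
      tr$center_mm <- tr$center_mm +
        stats::rnorm(3, 0, config$session_com_jitter_sd_mm)
      tr$amplitude <- tr$amplitude +
        stats::rnorm(1, 0, config$session_amplitude_jitter_sd)
    }
    tr
  })

  vol0 <- anat
  signal <- array(0, c(prod(dm), nt))
  for (tr in used) {
    w <- sphere_weights(tr, config, affine)
    if (!any(w > 0)) stop("ground-truth cluster lies outside the grid")
    reg <- condition_regressor(par, tr$condition_label)
    signal <- signal + as.vector(w) %o% (tr$amplitude * reg)
  }
  data <- array(as.vector(vol0) + signal, c(dm, nt))

  if (config$noise_sd > 0) {
    noise <- matrix(stats::rnorm(prod(dm) * nt), prod(dm), nt)
    if (config$noise_fwhm_mm > 0) {
      for (t in seq_len(nt)) {
        noise[, t] <- as.vector(gaussian_smooth_3d(
          array(noise[, t], dm), config$noise_fwhm_mm, config$voxel_size_mm))
      }
    }
    noise <- ar1_filter_scale(noise, config$ar1_rho, config$noise_sd)
    data <- data + array(noise, c(dm, nt))
  }

  motion <- matrix(0, nt, 6,
                   dimnames = list(NULL, c("rx_deg", "ry_deg", "rz_deg",
                                           "tx_mm", "ty_mm", "tz_mm")))
  if (is.function(config$motion_profile)) {
    motion <- config$motion_profile(nt)
    stopifnot(is.matrix(motion), nrow(motion) == nt, ncol(motion) == 6)
    colnames(motion) <- c("rx_deg", "ry_deg", "rz_deg", "tx_mm", "ty_mm", "tz_mm")
    for (t in seq_len(nt)) {
      if (any(motion[t, ] != 0)) {
        data[, , , t] <- apply_rigid(data[, , , t], motion[t, ], affine)
      }
    }
  }

  list(bold = bold4d(data, affine, par$tr_seconds, mask),
       motion = motion, truths = used, paradigm = par)
}

#' Simulate a full two-session dataset
#'
#' Applies [simulate_session()] over all subjects, both sessions and the
#' requested runs, with a distinct derived seed per (subject, session, run).
#'
#' @param config a `simulation_config`.
#' @param truths named per-run lists of ground-truth clusters; defaults to
#'   [default_truths()].
#' @param runs runs to simulate.
#' @return object of class `trt_dataset`: nested list
#'   `$sessions[[subject]][[session]][[run]]`, plus `config`, `runs`.
#' @export
simulate_dataset <- function(config, truths = NULL, runs = paste0("run", 1:5)) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(truths)) truths <- default_truths(config, runs)
  stopifnot(all(runs %in% names(truths)))
  sessions <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sessions[[s]] <- list()
    for (ses in 1:2) {
      sessions[[s]][[ses]] <- list()
      for (r in runs) {
        sessions[[s]][[ses]][[r]] <-
          simulate_session(config, s, ses, r, truths[[r]])
      }
    }
  }
  structure(list(sessions = sessions, config = config, runs = runs,
                 truths = truths), class = "trt_dataset")
}

#' @export
print.trt_dataset <- function(x, ...) {
  cat(sprintf("trt_dataset: %d subjects x 2 sessions x %d runs (%s)\n",
              x$config$n_subjects, length(x$runs),
              paste(x$runs, collapse = ", ")))
  invisible(x)
}
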