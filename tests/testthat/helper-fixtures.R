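# Shared fixtures, built once per test run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(fixture_cache[[name]])) fixture_cache[[name]] <- force(expr)
  fixture_cache[[name]]
}

# Small noiseless config: sessions are identical by construction.
ideal_config <- function(n_subjects = 1, grid = c(20, 20, 14), seed = 11) {
  simulation_config(n_subjects = n_subjects, grid_shape = grid,
                    noise_sd = 0, noise_fwhm_mm = 0,
                    session_com_jitter_sd_mm = 0,
                    session_amplitude_jitter_sd = 0, seed = seed)
}

# One noiseless run1 session plus its truths (cached).
ideal_session <- function() {
  cached("ideal_session", {
    cfg <- ideal_config()
    truths <- default_truths(cfg, "run1")
    list(cfg = cfg, truths = truths,
         s = simulate_session(cfg, 1, 1, "run1", truths$run1))
  })
}

# A noisy run2 session (AR(1) rho 0.4) for recovery tests (cached).
noisy_session <- function() {
  cached("noisy_session", {
    cfg <- simulation_config(n_subjects = 1, grid_shape = c(24, 24, 16),
                             noise_sd = 1, ar1_rho = 0.4, noise_fwhm_mm = 6,
                             seed = 21)
    truths <- default_truths(cfg, "run2")
    list(cfg = cfg, truths = truths,
         s = simulate_session(cfg, 1, 1, "run2", truths$run2))
  })
}

# A smooth random phantom with anatomy-like contrast, for registration tests.
smooth_phantom <- function(dm = c(24, 24, 16), seed = 5) {
  set.seed(seed)
  x <- array(stats::rnorm(prod(dm)), dm)
  fmritrt:::gaussian_smooth_3d(x, 12, 4) * 50 + 100
}

# Tiny two-condition paradigm for toy regression tests.
toy_paradigm <- function(n_rest = 4, n_task = 4, cycles = 3, tr = 2) {
  blocks <- data.frame(condition = "rest", duration_tr = n_rest)
  for (i in seq_len(cycles)) {
    blocks <- rbind(blocks,
                    data.frame(condition = c("task", "rest"),
                               duration_tr = c(n_task, n_rest)))
  }
  structure(list(run_id = "toy", tr_seconds = tr, blocks = blocks,
                 n_volumes = as.integer(sum(blocks$duration_tr)),
                 condition_labels = "task"), class = "task_paradigm")
}

# bold4d from a (time x voxels) matrix on a tiny grid.
toy_bold <- function(Y, tr = 2, dm = c(ncol(Y), 1, 1)) {
  stopifnot(prod(dm) == ncol(Y))
  nt <- nrow(Y)
  data <- array(t(Y), c(dm, nt))
  bold4d(data, diag(c(4, 4, 4, 1)), tr, array(TRUE, dm))
}
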