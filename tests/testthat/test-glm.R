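test_that("baseline polynomial order follows the 150-volume rule", {
  expect_identical(build_design(build_paradigm("run1"), "Std")$poly_order, 1L)  # 76
  expect_identical(build_design(build_paradigm("run2"), "Std")$poly_order, 2L)  # 173
  # boundary: exactly 150 volumes uses order 2
  p150 <- toy_paradigm(n_rest = 5, n_task = 5, cycles = 14, tr = 2)
  p150$n_volumes <- 150L
  p150$blocks <- rbind(p150$blocks, data.frame(condition = "rest",
                                               duration_tr = 150 - sum(p150$blocks$duration_tr)))
  expect_identical(build_design(p150, "Std")$poly_order, 2L)
})

test_that("censor flags use a strict greater-than rule", {
  expect_identical(censor_flags(c(0.1, 0.3, 0.6), 0.2), c(FALSE, TRUE, TRUE))
  expect_identical(censor_flags(c(0.1, 0.3, 0.6), 0.5), c(FALSE, FALSE, TRUE))
  expect_identical(censor_flags(0.2, 0.2), FALSE)
})

test_that("design variants add the expected columns and flags", {
  p <- toy_paradigm()
  n <- p$n_volumes - 1L
  d_std <- build_design(p, "Std")
  expect_identical(nrow(d_std$X), n)
  expect_false(any(d_std$censor))
  motion <- matrix(rnorm(n * 6, sd = 0.05), n, 6)
  d_mpc <- build_design(p, "MPC", motion = motion)
  expect_identical(ncol(d_mpc$X), ncol(d_std$X) + 6L)
  fd <- c(0, rep(0.1, n - 3), 0.3, 0.6)
  d_c2 <- build_design(p, "Cen2", fd = fd)
  expect_identical(sum(d_c2$censor), 2L)
  d_c5 <- build_design(p, "Cen5", fd = fd)
  expect_identical(sum(d_c5$censor), 1L)
  expect_error(build_design(p, "MPC"))
  expect_error(build_design(p, "Cen2"))
})

test_that("OLS recovers an exact linear model and its t-map matches a brute-force solve", {
  p <- toy_paradigm()
  d <- build_design(p, "Std")
  task <- d$X[, "task"]
  n <- length(task)
  set.seed(8)
  Y <- cbind(2 * task + 1,
             0.5 * task + rnorm(n, sd = 0.3),
             rnorm(n))
  fit <- fit_ols(toy_bold(Y), d)
  # voxel 1: exact model
  expect_equal(fit$betas$task[1, 1, 1], 2, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals[1, 1, 1, ])), 1e-10)
  expect_identical(fit$dof, n - ncol(d$X))
  # independent normal-equations oracle for every voxel
  X <- d$X
  XtXi <- solve(t(X) %*% X)
  for (v in 2:3) {   # voxel 1 is exact (zero residual), checked above
    b <- XtXi %*% t(X) %*% Y[, v]
    res <- Y[, v] - X %*% b
    s2 <- sum(res^2) / (n - ncol(X))
    t_or <- b[1] / sqrt(s2 * XtXi[1, 1])
    expect_equal(fit$tmap$task[v, 1, 1], t_or, tolerance = 1e-10,
                 info = paste("voxel", v))
  }
})

test_that("adding motion covariates never increases the residual sum of squares", {
  p <- toy_paradigm()
  n <- p$n_volumes - 1
  set.seed(12)
  motion <- matrix(rnorm(n * 6, sd = 0.1), n, 6)
  Y <- matrix(rnorm(n * 4), n, 4)
  run <- toy_bold(Y)
  rss <- function(fit) sum(fit$residuals^2)
  f_std <- fit_ols(run, build_design(p, "Std"))
  f_mpc <- fit_ols(run, build_design(p, "MPC", motion = motion))
  expect_lte(rss(f_mpc), rss(f_std) + 1e-10)
})

test_that("censoring signal-free volumes leaves noiseless betas unchanged", {
  p <- toy_paradigm()
  d <- build_design(p, "Std")
  task <- d$X[, "task"]
  Y <- cbind(3 * task + 2)
  n <- length(task)
  fd <- rep(0, n); fd[which(task < 1e-8)[2:3]] <- 0.4   # censor two rest volumes
  d_cen <- build_design(p, "Cen2", fd = fd)
  f_all <- fit_ols(toy_bold(Y), d)
  f_cen <- fit_ols(toy_bold(Y), d_cen)
  expect_equal(f_cen$betas$task[1, 1, 1], f_all$betas$task[1, 1, 1],
               tolerance = 1e-10)
  expect_identical(f_cen$dof, f_all$dof - 2L)
})

test_that("AR(1) prewhitening reduces to OLS on white noise", {
  p <- toy_paradigm(n_rest = 5, n_task = 5, cycles = 15)  # 155 volumes
  d <- build_design(p, "Std")
  task <- d$X[, "task"]
  n <- length(task)
  set.seed(3)
  dm <- c(6, 6, 3)
  Y <- sapply(seq_len(prod(dm)), function(i) 0.8 * task + rnorm(n))
  run <- toy_bold(Y, dm = dm)
  t_ols <- as.vector(fit_ols(run, d)$tmap$task)
  t_rml <- as.vector(fit_reml_ar1(run, d)$tmap$task)
  expect_lt(sqrt(mean((t_ols - t_rml)^2)) / sqrt(mean(t_ols^2)), 0.02)
})

test_that("AR(1) coefficient and whitened residuals are recovered at rho 0.4", {
  fix <- noisy_session()
  mc <- motion_correct_run(fix$s$bold, "NoMoCo")
  d <- build_design(fix$s$paradigm, "REML")
  fit <- fit_reml_ar1(mc$bold, d)
  rho <- attr(fit, "rho")[fix$s$bold$mask]
  expect_lt(abs(stats::median(rho) - 0.4), 0.1)
  # prewhitened residuals are close to temporally white
  res <- matrix(fit$residuals, ncol = dim(fit$residuals)[4])
  res <- res[fix$s$bold$mask, ]
  lag1 <- apply(res[seq(1, nrow(res), by = 37), ], 1, function(x)
    stats::cor(x[-1], x[-length(x)]))
  expect_lt(abs(stats::median(lag1)), 0.1)
})

test_that("beta at the cluster center recovers the injected amplitude without noise", {
  fix <- ideal_session()
  mc <- motion_correct_run(fix$s$bold, "NoMoCo")
  fit <- fit_ols(mc$bold, build_design(fix$s$paradigm, "Std"))
  truth <- fix$truths$run1[[1]]
  v <- round(truth$center_mm / fix$cfg$voxel_size_mm) + 1
  expect_equal(fit$betas$task[v[1], v[2], v[3]], truth$amplitude,
               tolerance = 1e-6)
})
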