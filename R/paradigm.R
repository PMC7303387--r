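#' Block-design task paradigms for the five acquisition runs
#'
#' Returns the ordered rest/task block structure of one of the five
#' block-design runs of the two-session cohort the package emulates:
#' overt word repetition (run1), covert verb generation (run2), overt verb
#' generation (run3), finger/foot/lip motor (run4) and visual landmark /
#' detection (run5). The overt-speech runs (1 and 3) were acquired with
#' sparse sampling and are modelled as plain block designs at an effective
#' TR of 5 s; the remaining runs use TR = 2.5 s.
#'
#' @param run_id one of `"run1" ... "run5"`.
#' @return an object of class `task_paradigm`: a list with `run_id`,
#'   `tr_seconds`, `blocks` (data.frame with `condition`, `duration_tr`),
#'   `n_volumes` and `condition_labels` (task conditions, excluding rest).
#' @examples
#' p <- build_paradigm("run1")
#' p$n_volumes  # 76
#' @export
build_paradigm <- function(run_id) {
  run_id <- match.arg(run_id, c("run1", "run2", "run3", "run4", "run5"))
  blk <- function(condition, duration_tr) data.frame(condition = condition,
                                                     duration_tr = duration_tr)
  cyc <- function(n, ...) do.call(rbind, rep(list(blk(...)), n))
  blocks <- switch(run_id,
    run1 = rbind(blk("rest", 4), cyc(6, c("task", "rest"), c(6, 6))),
    run2 = rbind(blk("rest", 5), cyc(7, c("task", "rest"), c(12, 12))),
    run3 = rbind(blk("rest", 4), cyc(7, c("task", "rest"), c(6, 6))),
    run4 = rbind(blk("rest", 4), cyc(10, c("finger", "foot", "lips"), c(6, 6, 6))),
    run5 = rbind(blk("rest", 10),
                 cyc(8, c("landmark", "rest", "detection", "rest"), c(6, 7, 6, 7)),
                 blk("rest", 20))
  )
  rownames(blocks) <- NULL
  tr <- if (run_id %in% c("run1", "run3")) 5 else 2.5
  structure(list(
    run_id = run_id,
    tr_seconds = tr,
    blocks = blocks,
    n_volumes = as.integer(sum(blocks$duration_tr)),
    condition_labels = setdiff(unique(blocks$condition), "rest")
  ), class = "task_paradigm")
}

#' @export
print.task_paradigm <- function(x, ...) {
  cat(sprintf("Task paradigm %s: %d volumes, TR %.1f s, conditions: %s\n",
              x$run_id, x$n_volumes, x$tr_seconds,
              paste(x$condition_labels, collapse = ", ")))
  invisible(x)
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard difference-of-gammas impulse response (response peak 6 s,
#' undershoot peak 16 s, undershoot ratio 1/6), normalised so its maximum
#' is 1. Any smooth causal HRF suffices for this package because the data
#' generator and the regression share the same shape.
#'
#' @param time_s non-negative time grid in seconds.
#' @return HRF amplitude at each time point.
#' @export
canonical_hrf <- function(time_s) {
  if (any(time_s < 0)) stop("time_s must be non-negative")
  a1 <- 6; a2 <- 16; b <- 1; ratio <- 1 / 6
  h <- dgamma(time_s, shape = a1, rate = b) - ratio * dgamma(time_s, shape = a2, rate = b)
  # normalise against the peak of the continuous response, not the grid max,
  # so coarse grids (TR sampling) keep a consistent scale
  tfine <- seq(0, 32, by = 0.01)
  peak <- max(dgamma(tfine, a1, b) - ratio * dgamma(tfine, a2, b))
  h / peak
}

#' Task regressor for one condition of a paradigm
#'
#' Builds the boxcar stimulus function of the condition's blocks on a fine
#' time grid, convolves it with [canonical_hrf()], and samples the result at
#' the paradigm's TR. A condition absent from the paradigm yields an
#' all-zero regressor.
#'
#' @param paradigm a `task_paradigm`.
#' @param condition condition label.
#' @param dt_s fine-grid step for the convolution (seconds).
#' @return numeric vector of length `paradigm$n_volumes`.
#' @export
condition_regressor <- function(paradigm, condition, dt_s = 0.1) {
  stopifnot(inherits(paradigm, "task_paradigm"))
  tr <- paradigm$tr_seconds
  total_s <- paradigm$n_volumes * tr
  tfine <- seq(0, total_s, by = dt_s)
  box <- numeric(length(tfine))
  onset <- 0
  for (b in seq_len(nrow(paradigm$blocks))) {
    dur <- paradigm$blocks$duration_tr[b] * tr
    if (paradigm$blocks$condition[b] == condition) {
      box[tfine >= onset & tfine < onset + dur] <- 1
    }
    onset <- onset + dur
  }
  hrf <- canonical_hrf(seq(0, 32, by = dt_s))
  conv <- convolve(box, rev(hrf), type = "open")[seq_along(tfine)] * dt_s
  # scale so a sustained block saturates near 1 (HRF integral normalisation)
  conv <- conv / (sum(hrf) * dt_s)
  sample_t <- (seq_len(paradigm$n_volumes) - 1) * tr
  conv[round(sample_t / dt_s) + 1]
}
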