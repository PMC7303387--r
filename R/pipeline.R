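# Factorial pipeline orchestration: enumerate processing combinations, run
# every stage over a two-session dataset, extract matched clusters and
# assemble the metric records.

#' @noRd
blur_label <- function(fwhm) sprintf("Blur%02d", as.integer(round(fwhm)))

#' Enumerate the factorial of processing pipelines
#'
#' Full Cartesian product of the requested methods of the four stages, in
#' deterministic lexicographic stage order (motion, smoothing, regression,
#' threshold). The full menu (4 x 5 x 5 x 4) yields 400 pipelines.
#'
#' @param motion motion-correction method labels.
#' @param smoothing smoothing FWHMs in mm.
#' @param regression regression variant labels.
#' @param threshold thresholding method labels.
#' @return data.frame with one row per pipeline and a `label` column
#'   (dot-joined 4-tuple, e.g. `"Rigid3D.Blur06.Std.Bon"`).
#' @export
enumerate_pipelines <- function(motion = c("NoMoCo", "2D3D", "Rigid3D", "Affine"),
                                smoothing = c(0, 3, 6, 9, 12),
                                regression = c("Std", "REML", "Cen2", "Cen5", "MPC"),
                                threshold = c("Bon", "FDR", "Clst", "AMPLE")) {
  stopifnot(length(motion) > 0, length(smoothing) > 0,
            length(regression) > 0, length(threshold) > 0)
  g <- expand.grid(threshold = threshold, regression = regression,
                   smoothing = smoothing, motion = motion,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("motion", "smoothing", "regression", "threshold")]
  g <- g[order(g$motion, g$smoothing, g$regression, g$threshold), ]
  rownames(g) <- NULL
  g$label <- paste(g$motion, blur_label(g$smoothing), g$regression,
                   g$threshold, sep = ".")
  g
}

#' Full-menu analysis bookkeeping
#'
#' Planned analysis-unit counts for a study: total activation-map analyses
#' (pipelines x maps x subjects x sessions) and the per-activation-type
#' count (pipelines x subjects x sessions).
#'
#' @param n_pipelines,n_maps,n_subjects,n_sessions sizes of the sweep.
#' @return list with `total` and `per_map`.
#' @export
planned_analyses <- function(n_pipelines, n_maps, n_subjects, n_sessions = 2) {
  list(total = n_pipelines * n_maps * n_subjects * n_sessions,
       per_map = n_pipelines * n_subjects * n_sessions)
}

# Activation-map tags of a run: one per task condition.
#' @noRd
map_tags <- function(run, paradigm) paste(run, paradigm$condition_labels, sep = ":")

#' Run the full test-retest study over a dataset
#'
#' For every pipeline x subject x session x run x condition: motion
#' correction, masked smoothing, regression, thresholding, then cluster
#' extraction. ROI prevalence masks are built per activation type across all
#' pipelines, subjects and sessions; clusters are ROI-filtered and matched
#' across the two sessions; and one metric record (PDAV, DCM, DSC) is
#' emitted per matched pair. Shared stage prefixes are computed once, and
#' per-unit failures are logged and skipped rather than aborting the sweep.
#'
#' @param dataset a `trt_dataset` from [simulate_dataset()].
#' @param motion,smoothing,regression,threshold method menus per stage
#'   (see [enumerate_pipelines()]; only `NoMoCo`/`Rigid3D` motion arms are
#'   implemented).
#' @param runs runs to analyse (default: all in the dataset).
#' @param min_cluster_voxels minimum cluster extent (default 12).
#' @param prevalence ROI mask prevalence (default 0.10).
#' @param match_dist_mm cluster-matching radius (default 10).
#' @param clst_n_iter Monte-Carlo iterations for the cluster-size table.
#' @param seed base seed for the Monte-Carlo thresholds (independent of the
#'   session being analysed, so identical sessions see identical
#'   thresholds).
#' @return object of class `trt_study`: `records` (one row per matched
#'   pair), `pipelines`, `rois`, `counts`, `errors`, `settings`.
#' @export
run_study <- function(dataset,
                      motion = c("NoMoCo", "Rigid3D"),
                      smoothing = c(0, 3, 6, 9, 12),
                      regression = c("Std", "REML", "Cen2", "Cen5", "MPC"),
                      threshold = c("Bon", "FDR", "Clst", "AMPLE"),
                      runs = NULL, min_cluster_voxels = 12,
                      prevalence = 0.10, match_dist_mm = 10,
                      clst_n_iter = 1000, seed = 1L) {
  stopifnot(inherits(dataset, "trt_dataset"))
  stopifnot(all(motion %in% c("NoMoCo", "Rigid3D")))
  if (is.null(runs)) runs <- dataset$runs
  stopifnot(all(runs %in% dataset$runs))
  pipes <- enumerate_pipelines(motion, smoothing, regression, threshold)
  cfg <- dataset$config
  atlas <- region_atlas(cfg)
  n_sub <- cfg$n_subjects
  need_params <- any(regression %in% c("Cen2", "Cen5", "MPC"))

  acts <- list()        # activation maps keyed by pipeline|subject|session|tag
  errors <- list()
  clst_tables <- new.env(parent = emptyenv())  # cached by smoothness bin
  n_attempted <- 0L

  for (s in seq_len(n_sub)) for (ses in 1:2) for (r in runs) {
    entry <- dataset$sessions[[s]][[ses]][[r]]
    par <- entry$paradigm
    mc <- list()
    for (m in motion) mc[[m]] <- motion_correct_run(entry$bold, m)
    params <- if ("Rigid3D" %in% motion) mc[["Rigid3D"]]$params
      else if (need_params) estimate_motion_params(entry$bold)
      else matrix(0, par$n_volumes - 1, 6)
    fd <- framewise_displacement(params)
    vs <- abs(diag(entry$bold$affine)[1:3])

    for (m in motion) for (fw in smoothing) {
      sm <- tryCatch(smooth_run(mc[[m]]$bold, fw), error = function(e) e)
      if (inherits(sm, "error")) {
        errors[[length(errors) + 1]] <- list(unit = c(s, ses, r, m, fw),
                                             message = conditionMessage(sm))
        next
      }
      for (v in regression) {
        n_attempted <- n_attempted + length(threshold) * length(par$condition_labels)
        stat <- tryCatch(
          fit_variant(sm, par, v, motion = params, fd = fd),
          error = function(e) e)
        if (inherits(stat, "error")) {
          errors[[length(errors) + 1]] <- list(
            unit = c(s, ses, r, m, fw, v), message = conditionMessage(stat))
          next
        }
        smo <- NULL
        tabl <- NULL
        if ("Clst" %in% threshold) {
          smo <- estimate_smoothness(stat$residuals, stat$mask, vs)
          bin <- as.character(round(smo$fwhm_geom_mm * 2) / 2)
          if (is.null(clst_tables[[bin]])) {
            clst_tables[[bin]] <- cluster_size_threshold(
              stat$mask, smo, vs, n_iter = clst_n_iter,
              seed = derive_seed(seed, round(smo$fwhm_geom_mm * 2)))
          }
          tabl <- clst_tables[[bin]]
        }
        for (th in threshold) for (cc in par$condition_labels) {
          key <- paste(m, blur_label(fw), v, th, s, ses,
                       paste(r, cc, sep = ":"), sep = "|")
          act <- tryCatch(
            apply_threshold(stat, th, condition = cc, atlas = atlas,
                            smoothness = smo, cluster_table = tabl),
            error = function(e) e)
          if (inherits(act, "error")) {
            errors[[length(errors) + 1]] <- list(
              unit = c(s, ses, r, m, fw, v, th, cc),
              message = conditionMessage(act))
            next
          }
          acts[[key]] <- act
        }
      }
    }
  }

  # ROI prevalence masks per activation type, across everything
  tags <- unique(vapply(strsplit(names(acts), "|", fixed = TRUE),
                        function(x) x[7], character(1)))
  rois <- list()
  for (tg in tags) {
    sel <- vapply(strsplit(names(acts), "|", fixed = TRUE),
                  function(x) x[7] == tg, logical(1))
    rois[[tg]] <- build_roi_mask(unname(acts[sel]), prevalence)
  }

  # cluster extraction, ROI filtering, matching, metrics
  records <- list()
  affine <- sim_affine(cfg)
  for (i in seq_len(nrow(pipes))) {
    pl <- pipes[i, ]
    for (s in seq_len(n_sub)) for (tg in tags) {
      k1 <- paste(pl$motion, blur_label(pl$smoothing), pl$regression,
                  pl$threshold, s, 1, tg, sep = "|")
      k2 <- paste(pl$motion, blur_label(pl$smoothing), pl$regression,
                  pl$threshold, s, 2, tg, sep = "|")
      if (is.null(acts[[k1]]) || is.null(acts[[k2]])) next
      cl1 <- filter_by_roi(find_clusters(acts[[k1]], min_cluster_voxels),
                           rois[[tg]], affine)
      cl2 <- filter_by_roi(find_clusters(acts[[k2]], min_cluster_voxels),
                           rois[[tg]], affine)
      pairs <- match_clusters(cl1, cl2, match_dist_mm)
      if (length(pairs) == 0) next
      pm <- pair_metrics(pairs)
      pm$subject <- s
      pm$map <- tg
      pm$motion <- pl$motion
      pm$smoothing <- blur_label(pl$smoothing)
      pm$regression <- pl$regression
      pm$threshold <- pl$threshold
      pm$pipeline <- pl$label
      records[[length(records) + 1]] <- pm
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(pdav_percent = numeric(0), dcm_mm = numeric(0),
               dsc = numeric(0), v1_ul = numeric(0), v2_ul = numeric(0),
               subject = integer(0), map = character(0),
               motion = character(0), smoothing = character(0),
               regression = character(0), threshold = character(0),
               pipeline = character(0))
  rownames(records) <- NULL

  n_maps <- length(tags)
  structure(list(
    records = records, pipelines = pipes, rois = rois,
    counts = list(
      planned = planned_analyses(nrow(pipes), n_maps, n_sub)$total,
      attempted = n_attempted,
      activation_maps = length(acts),
      matched_pairs = nrow(records),
      failed = length(errors)),
    errors = errors,
    settings = list(runs = runs, min_cluster_voxels = min_cluster_voxels,
                    prevalence = prevalence, match_dist_mm = match_dist_mm,
                    clst_n_iter = clst_n_iter, seed = seed)
  ), class = "trt_study")
}

#' @export
print.trt_study <- function(x, ...) {
  cat("Test-retest pipeline study\n")
  cat(sprintf("  pipelines: %d, activation maps: %d, matched pairs: %d\n",
              nrow(x$pipelines), x$counts$activation_maps,
              x$counts$matched_pairs))
  if (x$counts$failed > 0) {
    cat(sprintf("  failed units: %d (see $errors)\n", x$counts$failed))
  }
  invisible(x)
}

#' Stage-by-stage comparison report of a study
#'
#' Runs [summarize_stage()] for every stage with at least two methods, for
#' each of the three metrics, and returns the comparison and percent-better
#' tables.
#'
#' @param study a `trt_study`.
#' @param alpha significance level for corrected comparisons.
#' @return list with `comparisons`, `summary` (both data.frames) and
#'   `kruskal` (one row per stage x metric).
#' @export
stage_report <- function(study, alpha = 0.05) {
  stopifnot(inherits(study, "trt_study"))
  rec <- study$records
  comparisons <- list(); summaries <- list(); kw <- list()
  for (stg in c("motion", "smoothing", "regression", "threshold")) {
    if (length(unique(rec[[stg]])) < 2) next
    for (met in c("pdav_percent", "dcm_mm", "dsc")) {
      res <- summarize_stage(rec, stg, met, alpha = alpha)
      comparisons[[length(comparisons) + 1]] <- res$comparisons
      summaries[[length(summaries) + 1]] <- res$summary
      kw[[length(kw) + 1]] <- data.frame(stage = stg, metric = met,
                                         H = res$kruskal$H, p = res$kruskal$p)
    }
  }
  list(comparisons = if (length(comparisons)) do.call(rbind, comparisons),
       summary = if (length(summaries)) do.call(rbind, summaries),
       kruskal = if (length(kw)) do.call(rbind, kw))
}

#' @export
summary.trt_study <- function(object, alpha = 0.05, ...) {
  rep <- stage_report(object, alpha = alpha)
  structure(list(study = object, report = rep, alpha = alpha),
            class = "summary.trt_study")
}

#' @export
print.summary.trt_study <- function(x, ...) {
  print(x$study)
  cat(sprintf("\nMetric means over %d matched pairs:\n",
              nrow(x$study$records)))
  if (nrow(x$study$records)) {
    cat(sprintf("  PDAV %.1f%%, DCM %.2f mm, DSC %.3f\n",
                mean(x$study$records$pdav_percent),
                mean(x$study$records$dcm_mm),
                mean(x$study$records$dsc)))
  }
  if (!is.null(x$report$summary)) {
    cat(sprintf("\nPercent of comparisons significantly better (alpha = %g):\n",
                x$alpha))
    print(x$report$summary, row.names = FALSE)
  }
  invisible(x)
}

#' Long-format metric table for box plots
#'
#' @param study a `trt_study`.
#' @return data.frame with columns `metric`, `value`, `stage`, `method`,
#'   `map`, one row per (record, metric, stage).
#' @export
metric_long_table <- function(study) {
  rec <- study$records
  out <- list()
  for (met in c("pdav_percent", "dcm_mm", "dsc")) {
    for (stg in c("motion", "smoothing", "regression", "threshold")) {
      if (!nrow(rec)) next
      out[[length(out) + 1]] <- data.frame(
        metric = met, value = rec[[met]], stage = stg,
        method = as.character(rec[[stg]]), map = rec$map)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(metric = character(0), value = numeric(0),
               stage = character(0), method = character(0), map = character(0))
}
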