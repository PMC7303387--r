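# Readers and writers: NIfTI-1 volumes, BIDS-style event TSVs, motion TSVs,
# metric tables and JSON manifests.

#' Write a BOLD run as a NIfTI-1 file
#'
#' @param run a `bold4d`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_bold <- function(run, path) {
  stopifnot(inherits(run, "bold4d"))
  vs <- abs(diag(run$affine)[1:3])
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(vs, run$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a BOLD run from a NIfTI-1 file
#'
#' @param path NIfTI file.
#' @param mask optional logical 3D mask; defaults to voxels whose time
#'   series has positive variance.
#' @param tr_seconds TR override; defaults to the header pixdim.
#' @return a `bold4d`.
#' @export
read_bold <- function(path, mask = NULL, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))
  stopifnot(length(dim(data)) == 4)
  pd <- RNifti::pixdim(img)
  affine <- diag(c(pd[1:3], 1))
  if (is.null(tr_seconds)) tr_seconds <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  if (is.null(mask)) {
    v <- apply(data, 1:3, stats::var)
    mask <- v > 0
  }
  bold4d(data, affine, tr_seconds, mask)
}

#' Write a paradigm as a BIDS-style events TSV
#'
#' Columns `onset`, `duration` (seconds) and `trial_type`; rest blocks are
#' omitted.
#'
#' @param paradigm a `task_paradigm`.
#' @param path output TSV path.
#' @export
write_events <- function(paradigm, path) {
  onset <- 0
  rows <- list()
  for (b in seq_len(nrow(paradigm$blocks))) {
    dur <- paradigm$blocks$duration_tr[b] * paradigm$tr_seconds
    if (paradigm$blocks$condition[b] != "rest") {
      rows[[length(rows) + 1]] <- data.frame(
        onset = onset, duration = dur,
        trial_type = paradigm$blocks$condition[b])
    }
    onset <- onset + dur
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write motion parameters as a 6-column TSV
#'
#' Columns: three rotations (degrees) then three translations (mm), one row
#' per retained volume.
#'
#' @param params n x 6 matrix.
#' @param path output TSV path.
#' @export
write_motion_params <- function(params, path) {
  utils::write.table(as.data.frame(params), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' One NIfTI per (subject, session, run) plus events and true-motion TSVs,
#' and a JSON manifest recording the configuration seed and the
#' (post-jitter) ground-truth clusters.
#'
#' @param dataset a `trt_dataset`.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trt_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(dataset$config[
    setdiff(names(dataset$config), "motion_profile")]), members = list())
  for (s in seq_len(dataset$config$n_subjects)) for (ses in 1:2) {
    for (r in dataset$runs) {
      entry <- dataset$sessions[[s]][[ses]][[r]]
      stem <- sprintf("sub-%02d_ses-%d_%s", s, ses, r)
      write_bold(entry$bold, file.path(dir, paste0(stem, "_bold.nii.gz")))
      write_events(entry$paradigm, file.path(dir, paste0(stem, "_events.tsv")))
      write_motion_params(entry$motion,
                          file.path(dir, paste0(stem, "_motion.tsv")))
      manifest$members[[stem]] <- list(
        subject = s, session = ses, run = r,
        truths = lapply(entry$truths, unclass))
    }
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Write an activation map as a binary NIfTI
#'
#' @param act an `activation_map`.
#' @param path output path.
#' @export
write_activation_map <- function(act, path) {
  stopifnot(inherits(act, "activation_map"))
  img <- RNifti::asNifti(array(as.integer(act$active), dim(act$active)))
  vs <- abs(diag((act$affine %||% diag(4)))[1:3])
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a Monte-Carlo cluster-size table as TSV
#'
#' Columns: alpha, k, n_iter, seed.
#'
#' @param table a `cluster_size_table`.
#' @param path output TSV path.
#' @export
write_cluster_size_table <- function(table, path) {
  df <- data.frame(alpha = table$alpha, k = table$k,
                   n_iter = attr(table, "n_iter"), seed = attr(table, "seed"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write study outputs as tidy TSV tables
#'
#' Writes the matched-pair metric records, the stage comparison table, the
#' percent-better summary and the long-format (box-plot-ready) metric table.
#'
#' @param study a `trt_study`.
#' @param dir output directory.
#' @return vector of written paths, invisibly.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "trt_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  paths <- w(study$records, "metric_records.tsv")
  rep <- stage_report(study)
  if (!is.null(rep$comparisons)) paths <- c(paths, w(rep$comparisons, "comparisons.tsv"))
  if (!is.null(rep$summary)) paths <- c(paths, w(rep$summary, "percent_better.tsv"))
  if (!is.null(rep$kruskal)) paths <- c(paths, w(rep$kruskal, "kruskal.tsv"))
  paths <- c(paths, w(metric_long_table(study), "metrics_long.tsv"))
  jsonlite::write_json(study$counts, file.path(dir, "counts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(dir, "counts.json")))
}
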