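# Comparison of test-retest metric distributions across the methods of each
# processing stage.

#' Kruskal-Wallis test across method groups
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' k - 1 degrees of freedom (delegates to `stats::kruskal.test`). When every
#' value in every group is identical the test is undefined; (H = 0, p = 1)
#' is returned by convention.
#'
#' @param groups list of numeric vectors, one per method.
#' @return list with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) > 0))
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(pooled, factor(rep(seq_along(groups), lengths(groups))))
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Unpaired pooled-variance t test
#'
#' Two-sample Student's t (equal-variance), two-sided p (delegates to
#' `stats::t.test(var.equal = TRUE)`). Identical groups with zero pooled
#' variance return (t = 0, p = 1).
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with `t` and `p_raw`.
#' @export
unpaired_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p_raw = 1))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p_raw = tt$p.value)
}

#' Bonferroni multiplicity correction across methods and maps
#'
#' Raw p-values are multiplied by (number of method comparisons) x (number
#' of activation maps) and capped at 1.
#'
#' @param p_raw raw p-value(s).
#' @param n_method_comparisons pairwise comparisons within the stage.
#' @param n_activation_maps activation-map types analysed.
#' @return corrected p-value(s).
#' @export
correct_multiplicity <- function(p_raw, n_method_comparisons, n_activation_maps) {
  stopifnot(n_method_comparisons >= 1, n_activation_maps >= 1)
  pmin(1, p_raw * n_method_comparisons * n_activation_maps)
}

#' Cohen's d with an n1 + n2 pooled-variance denominator
#'
#' Effect size (mean(a) - mean(b)) / s_pooled with
#' s_pooled^2 = ((n1 - 1) s1^2 + (n2 - 1) s2^2) / (n1 + n2). The divisor
#' `n1 + n2` is the convention adopted throughout the package; the textbook
#' `n1 + n2 - 2` variant is available via `denominator`.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param denominator `"n1+n2"` (default) or `"n1+n2-2"`.
#' @return Cohen's d.
#' @export
cohens_d <- function(a, b, denominator = c("n1+n2", "n1+n2-2")) {
  denominator <- match.arg(denominator)
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2, n2 >= 2)
  den <- if (denominator == "n1+n2") n1 + n2 else n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / den
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' @noRd
metric_direction <- function(metric) {
  # lower is better for PDAV and DCM, higher for DSC
  switch(metric, pdav_percent = -1, dcm_mm = -1, dsc = 1,
         stop("unknown metric ", metric))
}

#' Compare the methods of one processing stage
#'
#' For each activation map and each pair of methods of the stage, metric
#' values are pooled across subjects and all combinations of the other three
#' stages, compared with a pooled-variance t test, Bonferroni-corrected
#' across (method pairs) x (activation maps), and accompanied by Cohen's d.
#' A method is "significantly better" in a comparison when the corrected p
#' is below `alpha` and its mean lies on the favorable side of the metric
#' (lower for PDAV and DCM, higher for DSC). The stage summary reports, per
#' method, the percentage of its comparisons in which it was significantly
#' better.
#'
#' @param records data.frame of matched-pair metrics with columns
#'   `pdav_percent`, `dcm_mm`, `dsc`, `map` (activation-map tag) and one
#'   column per stage (`motion`, `smoothing`, `regression`, `threshold`).
#' @param stage which stage's methods to compare.
#' @param metric `"pdav_percent"`, `"dcm_mm"` or `"dsc"`.
#' @param alpha significance level on corrected p-values.
#' @return list with `comparisons` (one row per map x method pair) and
#'   `summary` (per method: `n_comparisons`, `n_better`, `percent_better`),
#'   plus `kruskal` (the omnibus test on the pooled groups).
#' @export
summarize_stage <- function(records, stage = c("motion", "smoothing",
                                               "regression", "threshold"),
                            metric = c("pdav_percent", "dcm_mm", "dsc"),
                            alpha = 0.05) {
  stage <- match.arg(stage)
  metric <- match.arg(metric)
  stopifnot(all(c(metric, "map", stage) %in% names(records)))
  methods <- sort(unique(as.character(records[[stage]])))
  stopifnot(length(methods) >= 2)
  maps <- sort(unique(as.character(records$map)))
  n_pairs <- choose(length(methods), 2)
  dirn <- metric_direction(metric)

  rows <- list()
  for (mp in maps) {
    sub <- records[records$map == mp, ]
    for (i in seq_len(length(methods) - 1)) for (j in (i + 1):length(methods)) {
      a <- sub[[metric]][sub[[stage]] == methods[i]]
      b <- sub[[metric]][sub[[stage]] == methods[j]]
      if (length(a) < 2 || length(b) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          stage = stage, metric = metric, map = mp,
          method_a = methods[i], method_b = methods[j],
          n_a = length(a), n_b = length(b),
          mean_a = if (length(a)) mean(a) else NA_real_,
          mean_b = if (length(b)) mean(b) else NA_real_,
          t = NA_real_, p_raw = NA_real_, p_corrected = NA_real_,
          d = NA_real_, better = NA_character_)
        next
      }
      tt <- unpaired_ttest(a, b)
      pc <- correct_multiplicity(tt$p_raw, n_pairs, length(maps))
      d <- tryCatch(cohens_d(a, b), error = function(e) NA_real_)
      better <- NA_character_
      if (!is.na(pc) && pc < alpha) {
        diff <- mean(a) - mean(b)
        if (diff * dirn > 0) better <- methods[i]
        if (diff * dirn < 0) better <- methods[j]
      }
      rows[[length(rows) + 1]] <- data.frame(
        stage = stage, metric = metric, map = mp,
        method_a = methods[i], method_b = methods[j],
        n_a = length(a), n_b = length(b),
        mean_a = mean(a), mean_b = mean(b),
        t = tt$t, p_raw = tt$p_raw, p_corrected = pc, d = d, better = better)
    }
  }
  comparisons <- do.call(rbind, rows)

  summary <- do.call(rbind, lapply(methods, function(m) {
    inv <- comparisons$method_a == m | comparisons$method_b == m
    tested <- inv & !is.na(comparisons$p_raw)
    nb <- sum(comparisons$better[tested] == m, na.rm = TRUE)
    data.frame(stage = stage, metric = metric, method = m,
               n_comparisons = sum(tested), n_better = nb,
               percent_better = if (sum(tested)) 100 * nb / sum(tested) else 0)
  }))

  groups <- lapply(methods, function(m) records[[metric]][records[[stage]] == m])
  names(groups) <- methods
  kw <- if (all(lengths(groups) > 0)) kruskal_wallis(groups) else
    list(H = NA_real_, p = NA_real_)

  list(comparisons = comparisons, summary = summary, kruskal = kw)
}
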