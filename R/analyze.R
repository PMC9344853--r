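#' Analyze one feature: adjustment, spline fits, permutation inference
#'
#' Runs the full per-feature workflow: per-subject baseline adjustment,
#' one smoothing-spline fit per group, the studentized interval statistic,
#' a subject-level label-permutation null, empirical p-values,
#' Benjamini-Hochberg adjustment across the feature's intervals, and
#' significant-interval calls at level `alpha`.
#'
#' Subjects whose series cannot be adjusted (non-positive values under
#' `log_ratio`, zero range under `min_max`, fewer than 2 usable points)
#' are dropped with a warning; the feature fails if either group is left
#' with fewer than 2 subjects.
#'
#' @param dataset a [longitudinal_dataset()].
#' @param feature_id feature to analyze (must be in `dataset$features`).
#' @param adjust baseline adjustment: `"min_max"` (default), `"log_ratio"`
#'   or `"none"`.
#' @param baseline `"first_sample"` or `"explicit"` (with `baseline_at`),
#'   used by `log_ratio`.
#' @param baseline_at explicit baseline time.
#' @param outlier_mad_k optional MAD multiplier for pre-min-max outlier
#'   removal ([filter_outliers_mad()]); `NULL` (default) disables it.
#' @param minmax_scope scope of the min-max affine map: `"feature"`
#'   (default) rescales by the feature's min/max over all samples, which
#'   preserves between-group contrasts in temporal dynamic range;
#'   `"subject"` rescales each subject's series onto `[0, 1]`
#'   individually, which also equalizes per-subject amplitudes (see the
#'   methods vignette for when that matters).
#' @param backend spline backend, `"ssanova"` or `"gamm"`.
#' @param grid a [time_grid()], or `NULL` for the default unit-step grid
#'   over the time range shared by both groups.
#' @param B number of permutations (default 1000).
#' @param alpha significance level for the BH-adjusted p-values (0.05).
#' @param seed integer seed for the permutation draws.
#' @param lambda optional fixed smoothing parameter(s).
#' @param k spline basis dimension.
#' @param keep_null keep the pooled null values in the result (can be
#'   large: `B * (T - 1)` numbers).
#' @return object of class `feature_result`: list with `feature_id`,
#'   `intervals` (tibble with one row per grid interval: `feature_id`,
#'   `t_start`, `t_end`, `statistic`, `p_value`, `p_adjusted`,
#'   `significant`, `dominant_group`), `fit_group1`, `fit_group2`, `null`
#'   (if kept), `dropped_subjects`, `seed`.
#' @export
analyze_feature <- function(dataset, feature_id,
                            adjust = c("min_max", "log_ratio", "none"),
                            baseline = "first_sample", baseline_at = NULL,
                            outlier_mad_k = NULL,
                            minmax_scope = c("feature", "subject"),
                            backend = c("ssanova", "gamm"),
                            grid = NULL, B = 1000, alpha = 0.05, seed = 1,
                            lambda = NULL, k = 50, gamma = 1.4,
                            keep_null = FALSE) {
  adjust <- match.arg(adjust)
  backend <- match.arg(backend)
  if (!inherits(dataset, "longitudinal_dataset"))
    abort_argument("`dataset` must be a longitudinal_dataset.")
  if (!feature_id %in% dataset$features)
    abort_argument(sprintf("feature '%s' not found.", feature_id))

  y <- dataset$values[feature_id, ]
  md <- dataset$metadata
  levels2 <- dataset$group_levels

  minmax_scope <- match.arg(minmax_scope)
  adj <- adjust_feature(y, md, method = adjust, baseline = baseline,
                        baseline_at = baseline_at,
                        outlier_mad_k = outlier_mad_k,
                        minmax_scope = minmax_scope)
  dropped <- attr(adj, "dropped")
  if (nrow(dropped))
    rlang::warn(sprintf("feature '%s': dropped %d subject(s) during adjustment (%s).",
                        feature_id, nrow(dropped),
                        paste(dropped$subject_id, collapse = ", ")),
                class = "lontide_dropped_subjects")

  grp_of <- vapply(adj, `[[`, "", "group")
  n_per_group <- table(factor(grp_of, levels = levels2))
  if (any(n_per_group < 2L))
    abort_design(sprintf("feature '%s': group '%s' has %d subject(s) after adjustment (need >= 2).",
                         feature_id, names(n_per_group)[which.min(n_per_group)],
                         min(n_per_group)))

  time <- unlist(lapply(adj, `[[`, "times"), use.names = FALSE)
  value <- unlist(lapply(adj, `[[`, "values"), use.names = FALSE)
  subj <- rep(vapply(adj, `[[`, "", "subject_id"),
              vapply(adj, function(s) length(s$times), 0L))
  group <- rep(grp_of, vapply(adj, function(s) length(s$times), 0L))

  for (g in levels2) {
    if (length(unique(time[group == g])) < 4L)
      abort_fit(sprintf("feature '%s': group '%s' has < 4 distinct timepoints.",
                        feature_id, g))
  }

  if (is.null(grid)) {
    sub_md <- data.frame(time = time, group = group)
    grid <- default_time_grid(sub_md, levels2)
  } else if (!inherits(grid, "time_grid")) {
    grid <- time_grid(grid)
  }

  eng <- spline_engine(time, value, subj, grid$points, k = k)
  s1 <- unique(subj[group == levels2[1]])
  s2 <- unique(subj[group == levels2[2]])
  f1 <- fit_subset(eng, s1, backend = backend, lambda = lambda, gamma = gamma)
  f2 <- fit_subset(eng, s2, backend = backend, lambda = lambda, gamma = gamma)
  observed <- stat_from_curves(f1$eta, f1$se, f2$eta, f2$se)

  subj_group <- unique(data.frame(subject_id = subj, group = group))
  nul <- null_from_engine(eng, subj_group, grid, B, backend, seed,
                          levels2, lambda, gamma)
  p <- empirical_pvalues(observed, nul$values)
  p_adj <- bh_adjust(p)
  dominant <- ifelse(observed > 0, levels2[1],
                     ifelse(observed < 0, levels2[2], "none"))

  intervals <- tibble::tibble(
    feature_id = feature_id,
    t_start = grid$t_start,
    t_end = grid$t_end,
    statistic = observed,
    p_value = p,
    p_adjusted = p_adj,
    significant = p_adj < alpha,
    dominant_group = dominant)

  structure(list(feature_id = feature_id,
                 intervals = intervals,
                 fit_group1 = fit_to_public(f1, levels2[1], backend, grid),
                 fit_group2 = fit_to_public(f2, levels2[2], backend, grid),
                 null = if (keep_null) {
                   structure(list(values = nul$values, B = B,
                                  n_intervals = grid$n_intervals,
                                  redraws = nul$redraws),
                             class = "null_distribution")
                 },
                 dropped_subjects = dropped,
                 alpha = alpha, seed = seed),
            class = "feature_result")
}

fit_to_public <- function(fit, group, backend, grid) {
  structure(list(group = group, backend = backend, lambda = fit$lambda,
                 eta_hat = fit$eta, se = fit$se, n_points = fit$n_points,
                 edf = fit$edf, degenerate = fit$degenerate, grid = grid),
            class = "group_spline_fit")
}

#' @export
print.feature_result <- function(x, ...) {
  n_sig <- sum(x$intervals$significant)
  cat(sprintf("<feature_result> '%s': %d/%d intervals significant at alpha=%g\n",
              x$feature_id, n_sig, nrow(x$intervals), x$alpha))
  if (n_sig > 0) {
    sig <- x$intervals[x$intervals$significant, ]
    cat(sprintf("  significant span(s): %s\n",
                paste(collapse_runs(sig$t_start, sig$t_end), collapse = ", ")))
  }
  invisible(x)
}

collapse_runs <- function(t_start, t_end) {
  if (length(t_start) == 0L) return(character())
  brk <- c(TRUE, t_start[-1] != t_end[-length(t_end)])
  run <- cumsum(brk)
  vapply(split(seq_along(run), run), function(ix) {
    sprintf("[%g, %g]", t_start[ix[1]], t_end[ix[length(ix)]])
  }, "")
}

#' Analyze every feature of a dataset
#'
#' Batch driver over [analyze_feature()]. Each feature gets a
#' deterministic child seed derived from `seed` and its index, so results
#' are reproducible and independent of feature order and of the worker
#' count. Features that fail (e.g. too few subjects after adjustment) are
#' recorded and skipped, never aborting the run.
#'
#' @inheritParams analyze_feature
#' @param features feature IDs to analyze; `NULL` = all.
#' @param bh_scope `"feature"` (BH across each feature's intervals, the
#'   default) or `"global"` (BH across all features x intervals jointly).
#' @param workers number of parallel workers (forked; features are
#'   independent).
#' @param verbose print progress.
#' @return object of class `lontide_results`: list with `results` (long
#'   tibble, one row per feature x interval), `skipped` (tibble of
#'   feature_id/reason), and `config`.
#' @export
analyze_dataset <- function(dataset, features = NULL,
                            adjust = c("min_max", "log_ratio", "none"),
                            baseline = "first_sample", baseline_at = NULL,
                            outlier_mad_k = NULL,
                            minmax_scope = c("feature", "subject"),
                            backend = c("ssanova", "gamm"),
                            grid = NULL, B = 1000, alpha = 0.05, seed = 1,
                            bh_scope = c("feature", "global"),
                            lambda = NULL, k = 50, gamma = 1.4, workers = 1,
                            verbose = FALSE) {
  adjust <- match.arg(adjust)
  minmax_scope <- match.arg(minmax_scope)
  backend <- match.arg(backend)
  bh_scope <- match.arg(bh_scope)
  if (is.null(features)) features <- dataset$features
  missing <- setdiff(features, dataset$features)
  if (length(missing))
    abort_argument(sprintf("unknown feature(s): %s.",
                           paste(head(missing, 5), collapse = ", ")))

  run_one <- function(i) {
    fid <- features[i]
    fs <- child_seed(seed, i)
    res <- tryCatch(
      suppressWarnings(analyze_feature(
        dataset, fid, adjust = adjust, baseline = baseline,
        baseline_at = baseline_at, outlier_mad_k = outlier_mad_k,
        minmax_scope = minmax_scope,
        backend = backend, grid = grid, B = B, alpha = alpha,
        seed = fs, lambda = lambda, k = k, gamma = gamma)),
      error = identity)
    if (verbose && i %% 10L == 0L)
      message(sprintf("  ... %d/%d features", i, length(features)))
    res
  }

  idx <- seq_along(features)
  fits <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, run_one, mc.cores = workers)
  } else {
    lapply(idx, run_one)
  }

  ok <- !vapply(fits, inherits, TRUE, "error")
  skipped <- tibble::tibble(
    feature_id = features[!ok],
    reason = vapply(fits[!ok], conditionMessage, ""))
  results <- if (any(ok)) {
    do.call(rbind, lapply(fits[ok], `[[`, "intervals"))
  } else {
    tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(result_columns))),
      result_columns))
  }

  if (bh_scope == "global" && nrow(results)) {
    results$p_adjusted <- bh_adjust(results$p_value)
    results$significant <- results$p_adjusted < alpha
  }

  structure(list(results = tibble::as_tibble(results),
                 skipped = skipped,
                 config = list(adjust = adjust, baseline = baseline,
                               minmax_scope = minmax_scope,
                               backend = backend, B = B, alpha = alpha,
                               seed = seed, bh_scope = bh_scope, k = k,
                               n_features = length(features))),
            class = "lontide_results")
}

#' @export
print.lontide_results <- function(x, ...) {
  n_feat <- length(unique(x$results$feature_id))
  cat(sprintf("<lontide_results> %d features analyzed (%d skipped), backend=%s, B=%d\n",
              n_feat, nrow(x$skipped), x$config$backend, x$config$B))
  if (nrow(x$results)) {
    sig_by_feat <- tapply(x$results$significant, x$results$feature_id, sum)
    cat(sprintf("  features with >= 1 significant interval: %d\n",
                sum(sig_by_feat > 0)))
  }
  invisible(x)
}
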