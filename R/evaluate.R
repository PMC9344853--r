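#' Score one feature's interval calls against ground truth
#'
#' Builds the per-interval confusion matrix over the tested intervals:
#' an interval is truly different when it lies inside the truth window.
#' Sensitivity is `TP / (TP + FN)` and specificity `TN / (TN + FP)`;
#' either is `NA` when its denominator is zero (e.g. sensitivity of a
#' null feature with no truly different intervals).
#'
#' @param intervals data frame with columns `t_start`, `t_end`,
#'   `significant` for one feature (e.g. a `feature_result`'s `intervals`).
#' @param truth the truly-different window as a `c(lo, hi)` vector, a
#'   truth tibble with `t_start`/`t_end` rows (as produced by
#'   [simulate_cohort()]), or `NULL` for a null feature.
#' @return one-row tibble: `TP`, `FP`, `TN`, `FN`, `sensitivity`,
#'   `specificity`.
#' @examples
#' iv <- tibble::tibble(t_start = 0:3, t_end = 1:4,
#'                      significant = c(FALSE, FALSE, TRUE, TRUE))
#' score_feature(iv, c(1, 3))  # TP=1, FN=1, FP=1, TN=1
#' @export
score_feature <- function(intervals, truth = NULL) {
  if (inherits(intervals, "feature_result")) intervals <- intervals$intervals
  need <- c("t_start", "t_end", "significant")
  if (!all(need %in% names(intervals)))
    abort_argument("`intervals` needs columns t_start, t_end, significant.")
  w <- truth_window(truth)
  truly <- if (is.null(w)) rep(FALSE, nrow(intervals)) else {
    intervals$t_start >= w[1] & intervals$t_end <= w[2]
  }
  called <- as.logical(intervals$significant)
  TP <- sum(called & truly); FP <- sum(called & !truly)
  FN <- sum(!called & truly); TN <- sum(!called & !truly)
  tibble::tibble(
    TP = TP, FP = FP, TN = TN, FN = FN,
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
}

truth_window <- function(truth) {
  if (is.null(truth)) return(NULL)
  if (is.numeric(truth)) {
    if (length(truth) != 2L || truth[1] >= truth[2])
      abort_argument("a numeric truth window must be c(lo, hi) with lo < hi.")
    return(truth)
  }
  if (is.data.frame(truth)) {
    if (nrow(truth) == 0L) return(NULL)
    return(c(min(truth$t_start), max(truth$t_end)))
  }
  abort_argument("`truth` must be NULL, c(lo, hi) or a truth data frame.")
}

#' Score every feature of a results table
#'
#' @param results long results tibble (from [analyze_dataset()], or its
#'   `results` element) with a `feature_id` column.
#' @param truth as in [score_feature()]; per-feature truth tibbles are
#'   matched by `feature_id`.
#' @return tibble with one row per feature: confusion counts plus
#'   sensitivity and specificity.
#' @export
score_results <- function(results, truth = NULL) {
  if (inherits(results, "lontide_results")) results <- results$results
  feats <- unique(results$feature_id)
  per_feature_truth <- is.data.frame(truth) && "feature_id" %in% names(truth)
  rows <- lapply(feats, function(f) {
    iv <- results[results$feature_id == f, ]
    tr <- if (per_feature_truth) truth[truth$feature_id == f, ] else truth
    cbind(tibble::tibble(feature_id = f), score_feature(iv, tr))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Run the five-pattern simulation benchmark
#'
#' For each requested combination of pattern, spline backend and baseline
#' adjustment: simulates a cohort, analyzes every feature, scores the
#' calls against the simulation truth, and averages per-feature
#' sensitivity (over features where it is defined, i.e. excluding the
#' pattern-5 negative control) and specificity (over all features).
#'
#' Default scale is deliberately reduced relative to a full study
#' (`n_features = 50`, `B = 200`); the scale used is stamped into every
#' output row. Cohort and analysis seeds are derived deterministically
#' from `seed`, per pattern, so backends and adjustments within one call
#' see identical cohorts.
#'
#' @param patterns integer subset of 1:5.
#' @param backends subset of `c("ssanova", "gamm")`.
#' @param adjust subset of `c("min_max", "log_ratio", "none")`.
#' @param sigma noise SD (scalar or vector to sweep).
#' @param n_features features per pattern.
#' @param B permutations per feature.
#' @param n_subjects_per_group subjects per group.
#' @param alpha significance level.
#' @param seed master seed.
#' @param k spline basis dimension.
#' @param workers parallel workers for the per-feature loop.
#' @param verbose print progress.
#' @return tibble with one row per (pattern, backend, adjust, sigma):
#'   mean sensitivity/specificity plus the scale columns
#'   `n_features`, `n_analyzed`, `B`, `seed`.
#' @export
run_benchmark <- function(patterns = 1:5, backends = "ssanova",
                          adjust = "min_max", minmax_scope = "feature",
                          sigma = 5,
                          n_features = 50, B = 200,
                          n_subjects_per_group = 10, alpha = 0.05,
                          seed = 1, k = 50, gamma = 1.4, workers = 1,
                          verbose = FALSE) {
  stopifnot(all(patterns %in% 1:5))
  rows <- list()
  for (sg in sigma) {
    for (p in patterns) {
      cfg <- simulation_config(pattern = p, sigma = sg,
                               n_subjects_per_group = n_subjects_per_group,
                               n_features = n_features,
                               seed = child_seed(seed, p + 1000L * match(sg, sigma)))
      cohort <- simulate_cohort(cfg)
      for (bk in backends) {
        for (adj in adjust) {
          if (verbose)
            message(sprintf("pattern %d, sigma %g, backend %s, adjust %s ...",
                            p, sg, bk, adj))
          res <- analyze_dataset(cohort$dataset, adjust = adj,
                                 minmax_scope = minmax_scope, backend = bk,
                                 B = B, alpha = alpha,
                                 seed = child_seed(seed, 37L * p + match(bk, backends)),
                                 k = k, gamma = gamma, workers = workers,
                                 verbose = verbose)
          sc <- score_results(res$results, cohort$window)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            pattern = p, backend = bk, adjust = adj, sigma = sg,
            mean_sensitivity = mean(sc$sensitivity, na.rm = TRUE),
            mean_specificity = mean(sc$specificity, na.rm = TRUE),
            n_features = n_features, n_analyzed = nrow(sc),
            n_skipped = nrow(res$skipped), B = B, alpha = alpha,
            seed = seed)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$mean_sensitivity[is.nan(out$mean_sensitivity)] <- NA_real_
  out
}
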