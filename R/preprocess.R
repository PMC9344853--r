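#' Per-subject baseline adjustment
#'
#' Interpersonal levels of an omics feature commonly differ far more than
#' within-person changes, so each subject's series is put on a common
#' footing before curve fitting. Two adjustments are provided:
#'
#' * **log-ratio** (`adjust_log_ratio()`): `y_adj(t) = log(y(t) / y(t_b))`
#'   with natural log, where `t_b` is the subject's baseline timepoint
#'   (typically the sample just before a perturbation). The value at the
#'   baseline is exactly 0. Requires strictly positive measurements.
#' * **min-max** (`adjust_min_max()`): `y_adj(t) = (y(t) - min y) / (max y -
#'   min y)`, mapping each subject's series onto `[0, 1]` with both
#'   endpoints attained. Emphasizes the temporal pattern rather than the
#'   amplitude; sensitive to outliers, so an optional MAD filter
#'   ([filter_outliers_mad()]) can be applied first.
#'
#' Downstream p-values do not depend on the log base, nor on any positive
#' scaling of the raw series: the interval statistic is studentized and
#' the permutation null is built from the same transformed data.
#'
#' @param times numeric vector of observation times for one subject.
#' @param values numeric vector of raw measurements aligned to `times`.
#' @param baseline_time the subject's baseline timepoint; must be one of
#'   `times`. See [choose_baseline()].
#' @return An object of class `adjusted_series`: list with `times`
#'   (sorted increasing), `values` (adjusted), and `method`.
#' @examples
#' adjust_log_ratio(c(0, 10, 20), c(10, 20, 5), baseline_time = 0)
#' adjust_min_max(c(0, 10, 20), c(2, 4, 8))
#' @export
adjust_log_ratio <- function(times, values, baseline_time) {
  check_series(times, values)
  if (any(values <= 0))
    abort_domain("log-ratio adjustment requires strictly positive values; found a value <= 0.")
  b <- which(times == baseline_time)
  if (length(b) != 1L)
    abort_argument(sprintf("baseline_time %g is not an observed timepoint.", baseline_time))
  adj <- log(values / values[b])
  new_adjusted_series(times, adj, "log_ratio")
}

#' @rdname adjust_log_ratio
#' @export
adjust_min_max <- function(times, values) {
  check_series(times, values)
  if (length(values) < 2L)
    abort_argument("min-max adjustment needs at least 2 points.")
  rng <- range(values)
  if (diff(rng) == 0)
    rlang::abort(sprintf("constant series (all values = %g): min-max range is zero.", rng[1]),
                 class = c("lontide_degenerate_error", "lontide_error"))
  new_adjusted_series(times, (values - rng[1]) / diff(rng), "min_max")
}

new_adjusted_series <- function(times, values, method) {
  o <- order(times)
  structure(list(times = times[o], values = values[o], method = method),
            class = "adjusted_series")
}

check_series <- function(times, values) {
  if (length(times) != length(values))
    abort_argument("`times` and `values` must have equal length.")
  if (length(times) == 0L)
    abort_argument("empty series.")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    abort_argument("series contains non-finite times or values.")
  if (anyDuplicated(times))
    abort_argument("duplicate observation times within one subject's series.")
  invisible(TRUE)
}

#' Choose a subject's baseline timepoint
#'
#' @param times numeric vector of the subject's observation times.
#' @param strategy `"first_sample"` (the earliest observed time, the
#'   default) or `"explicit"` (use `at`).
#' @param at the explicit baseline time; must be observed for the subject.
#' @return the baseline time (scalar).
#' @examples
#' choose_baseline(c(3, 0, 10))              # 0
#' choose_baseline(c(0, 10), "explicit", 10) # 10
#' @export
choose_baseline <- function(times, strategy = c("first_sample", "explicit"),
                            at = NULL) {
  strategy <- match.arg(strategy)
  if (length(times) == 0L) abort_argument("empty series.")
  if (strategy == "first_sample") return(min(times))
  if (is.null(at) || !is_scalar_number(at))
    abort_argument("strategy 'explicit' requires a numeric baseline time `at`.")
  if (!at %in% times)
    abort_argument(sprintf("explicit baseline time %g is not observed for this subject.", at))
  at
}

#' Flag outlying points in one subject's series by the MAD rule
#'
#' Marks points with `|value - median| > k * MAD` for removal prior to
#' min-max scaling, which is not robust to outliers. With the default
#' `k = 5` only gross outliers are removed. When the MAD is zero the
#' series is left untouched.
#'
#' @param values numeric vector.
#' @param k MAD multiplier (default 5).
#' @return logical vector, `TRUE` for points to keep.
#' @export
filter_outliers_mad <- function(values, k = 5) {
  if (!is_scalar_number(k) || k <= 0) abort_argument("`k` must be a positive number.")
  m <- stats::median(values)
  s <- stats::mad(values)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(values)))
  abs(values - m) <= k * s
}

# Adjust one feature's measurements subject by subject.
#
# Returns a list with one element per retained subject:
#   list(subject_id, group, times, values)
# plus attribute "dropped": data frame of (subject_id, reason) for subjects
# whose series could not be adjusted (non-positive values under log_ratio,
# zero range under min_max, < 2 usable points). Missing (NA) measurements
# are dropped per subject before adjustment.
adjust_feature <- function(y, metadata, method = c("min_max", "log_ratio", "none"),
                           baseline = "first_sample", baseline_at = NULL,
                           outlier_mad_k = NULL,
                           minmax_scope = c("feature", "subject")) {
  method <- match.arg(method)
  minmax_scope <- match.arg(minmax_scope)
  keep <- is.finite(y)
  feature_range <- NULL
  if (method == "min_max" && minmax_scope == "feature") {
    feature_range <- range(y[keep])
    if (diff(feature_range) == 0)
      rlang::abort("constant feature: min-max range is zero across all samples.",
                   class = c("lontide_degenerate_error", "lontide_error"))
  }
  subj <- split(which(keep), metadata$subject_id[keep])
  out <- list()
  dropped <- list()
  for (sid in names(subj)) {
    ix <- subj[[sid]]
    tt <- metadata$time[ix]
    yy <- y[ix]
    grp <- metadata$group[ix][1]
    if (!is.null(outlier_mad_k) && method == "min_max") {
      ok <- filter_outliers_mad(yy, outlier_mad_k)
      tt <- tt[ok]; yy <- yy[ok]
    }
    if (length(tt) < 2L) {
      dropped[[sid]] <- "fewer than 2 usable timepoints"
      next
    }
    res <- switch(method,
      none = tryCatch(new_adjusted_series(tt, yy, "none"), error = identity),
      min_max = if (is.null(feature_range)) {
        tryCatch(adjust_min_max(tt, yy), error = identity)
      } else {
        tryCatch(new_adjusted_series(
          tt, (yy - feature_range[1]) / diff(feature_range), "min_max"),
          error = identity)
      },
      log_ratio = tryCatch({
        b <- choose_baseline(tt,
                             strategy = if (identical(baseline, "explicit")) "explicit" else "first_sample",
                             at = baseline_at)
        adjust_log_ratio(tt, yy, b)
      }, error = identity))
    if (inherits(res, "error")) {
      dropped[[sid]] <- conditionMessage(res)
      next
    }
    out[[sid]] <- list(subject_id = sid, group = grp,
                       times = res$times, values = res$values)
  }
  attr(out, "dropped") <- if (length(dropped)) {
    data.frame(subject_id = names(dropped),
               reason = unlist(dropped, use.names = FALSE))
  } else {
    data.frame(subject_id = character(), reason = character())
  }
  out
}
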