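#' Studentized area-between-curves statistic per time interval
#'
#' For each grid interval `(t_j, t_j+1)` the statistic is the trapezoid
#' area between the two group curves over the interval, studentized by the
#' combined standard error:
#'
#' \deqn{s_j = \frac{(\hat\eta^{1}_j + \hat\eta^{1}_{j+1})/2 -
#'                  (\hat\eta^{2}_j + \hat\eta^{2}_{j+1})/2}
#'                 {\sqrt{((SE^{1}_j + SE^{1}_{j+1})/2)^2 +
#'                        ((SE^{2}_j + SE^{2}_{j+1})/2)^2}}}
#'
#' with the group-1-minus-group-2 sign convention: positive values mean
#' the group-1 curve sits above the group-2 curve on that interval. When
#' the numerator is exactly zero the statistic is zero.
#'
#' @param fit1,fit2 [fit_group_spline()] results for groups 1 and 2,
#'   evaluated on the same grid.
#' @param grid optional [time_grid()]; defaults to the grid carried by the
#'   fits, which must agree between them.
#' @return numeric vector of length `T - 1` (one statistic per interval).
#' @examples
#' f1 <- list(eta_hat = c(3, 5), se = c(1, 1), grid = time_grid(c(0, 1)))
#' f2 <- list(eta_hat = c(1, 1), se = c(1, 1), grid = time_grid(c(0, 1)))
#' interval_statistics(f1, f2)  # 3 / sqrt(2)
#' @export
interval_statistics <- function(fit1, fit2, grid = NULL) {
  g1 <- if (!is.null(grid)) grid else fit1$grid
  g2 <- if (!is.null(fit2$grid)) fit2$grid else g1
  if (is.null(g1)) abort_argument("no time grid available.")
  if (!is.null(g2) && !isTRUE(all.equal(g1$points, g2$points)))
    abort_argument("the two fits were evaluated on different grids.")
  if (length(fit1$eta_hat) != length(g1$points) ||
      length(fit2$eta_hat) != length(g1$points))
    abort_argument("fit predictions and grid have different lengths.")
  stat_from_curves(fit1$eta_hat, fit1$se, fit2$eta_hat, fit2$se)
}

# Vectorized Eq.-style statistic from raw curve vectors.
stat_from_curves <- function(eta1, se1, eta2, se2) {
  T <- length(eta1)
  i <- seq_len(T - 1L)
  j <- i + 1L
  num <- (eta1[i] + eta1[j]) / 2 - (eta2[i] + eta2[j]) / 2
  den <- sqrt(((se1[i] + se1[j]) / 2)^2 + ((se2[i] + se2[j]) / 2)^2)
  out <- numeric(T - 1L)
  nz <- num != 0
  out[nz] <- num[nz] / pmax(den[nz], .Machine$double.xmin)
  out
}

#' Permute group labels at the subject level
#'
#' Draws a uniformly random rearrangement of the subjects' group labels,
#' preserving group sizes. All longitudinal samples of a subject move
#' together, so within-subject correlation is preserved under the null.
#'
#' @param subjects data frame with columns `subject_id` and `group` (one
#'   row per subject), or a named character vector of groups.
#' @param rng_seed integer seed making the draw reproducible.
#' @return named character vector: `subject_id -> permuted group`.
#' @export
permute_group_labels <- function(subjects, rng_seed) {
  if (is.data.frame(subjects)) {
    labels <- stats::setNames(as.character(subjects$group),
                              as.character(subjects$subject_id))
  } else {
    labels <- subjects
  }
  if (is.null(names(labels)))
    abort_argument("`subjects` must carry subject IDs (names or a subject_id column).")
  counts <- table(labels)
  if (length(counts) != 2L || any(counts < 2L))
    abort_design("permutation requires two groups with >= 2 subjects each.")
  withr::with_seed(rng_seed, {
    stats::setNames(sample(unname(labels)), names(labels))
  })
}

#' Build the pooled permutation null for one feature
#'
#' Permutes the subject group labels `B` times; after each permutation the
#' two group splines are refitted on the permuted grouping and the
#' interval statistics recomputed. All `B x (T - 1)` permuted statistics
#' are pooled into one empirical null distribution for the feature.
#' Permutations whose refit fails (degenerate grouping) are redrawn; the
#' redraw count is recorded.
#'
#' @param times,values,subject_ids,groups vectors (one entry per adjusted
#'   observation) describing the feature's points.
#' @param grid a [time_grid()].
#' @param B number of permutations (>= 1).
#' @param backend spline backend, see [fit_group_spline()].
#' @param rng_seed integer seed; the same seed reproduces the null exactly.
#' @param group_levels length-2 vector fixing which label is group 1.
#' @param lambda,k passed to the spline fits.
#' @return object of class `null_distribution`: list with `values`
#'   (length `B * (T - 1)`), `B`, `n_intervals`, `redraws`.
#' @export
build_null <- function(times, values, subject_ids, groups, grid, B = 1000,
                       backend = c("ssanova", "gamm"), rng_seed = 1,
                       group_levels = NULL, lambda = NULL, k = 50, gamma = 1.4) {
  backend <- match.arg(backend)
  if (!inherits(grid, "time_grid")) grid <- time_grid(grid)
  if (B < 1L) abort_argument("B must be >= 1.")
  subj_group <- unique(data.frame(subject_id = as.character(subject_ids),
                                  group = as.character(groups)))
  if (is.null(group_levels)) group_levels <- sort(unique(subj_group$group))
  eng <- spline_engine(times, values, subject_ids, grid$points, k = k)
  res <- null_from_engine(eng, subj_group, grid, B, backend, rng_seed,
                          group_levels, lambda, gamma)
  structure(list(values = res$values, B = B,
                 n_intervals = grid$n_intervals, redraws = res$redraws),
            class = "null_distribution")
}

# Core permutation loop over a prebuilt engine. Label draws are generated
# up front under the seed so the null is reproducible and independent of
# fit internals.
null_from_engine <- function(eng, subj_group, grid, B, backend, rng_seed,
                             group_levels, lambda = NULL, gamma = 1.4) {
  labels <- stats::setNames(subj_group$group, subj_group$subject_id)
  n_int <- grid$n_intervals
  out <- matrix(NA_real_, n_int, B)
  max_draws <- 10L * B
  draws <- withr::with_seed(rng_seed, {
    replicate(max_draws, sample(unname(labels)), simplify = FALSE)
  })
  b <- 0L
  used <- 0L
  while (b < B && used < max_draws) {
    used <- used + 1L
    perm <- stats::setNames(draws[[used]], names(labels))
    s1 <- names(perm)[perm == group_levels[1]]
    s2 <- names(perm)[perm == group_levels[2]]
    stats_b <- tryCatch({
      f1 <- fit_subset(eng, s1, backend = backend, lambda = lambda, gamma = gamma)
      f2 <- fit_subset(eng, s2, backend = backend, lambda = lambda, gamma = gamma)
      stat_from_curves(f1$eta, f1$se, f2$eta, f2$se)
    }, error = function(e) NULL)
    if (is.null(stats_b) || any(!is.finite(stats_b))) next
    b <- b + 1L
    out[, b] <- stats_b
  }
  if (b < B)
    abort_fit(sprintf("permutation refits failed persistently (%d successes in %d draws).",
                      b, used))
  list(values = as.vector(out), redraws = used - B)
}

#' Empirical p-values from the pooled permutation null
#'
#' For an observed interval statistic `s`, the p-value is the fraction of
#' the pooled null (all intervals x all permutations of the same feature)
#' exceeding `s` when `s > 0`, or below `s` when `s < 0`; `s = 0` gives
#' `p = 1`. These are one-sided, sign-conditional probabilities; they are
#' not doubled. The smallest resolvable p-value is
#' `1 / (B * (T - 1))`, and exact zeros can occur.
#'
#' @param observed numeric vector of observed statistics (length `T - 1`).
#' @param null a `null_distribution` from [build_null()], or a numeric
#'   vector of pooled null values.
#' @return numeric vector of p-values in `[0, 1]`.
#' @examples
#' empirical_pvalues(c(2, 0.5, -2), c(-1, 0, 1))  # 0, 1/3, 0
#' @export
empirical_pvalues <- function(observed, null) {
  pool <- if (inherits(null, "null_distribution")) null$values else as.numeric(null)
  if (length(pool) == 0L) abort_argument("empty null distribution.")
  sv <- sort(pool)
  L <- length(sv)
  p <- rep(1, length(observed))
  pos <- observed > 0
  neg <- observed < 0
  # findInterval default counts null values <= s; left.open counts < s.
  p[pos] <- (L - findInterval(observed[pos], sv)) / L
  p[neg] <- findInterval(observed[neg], sv, left.open = TRUE) / L
  p
}

#' Benjamini-Hochberg adjustment for one feature's interval p-values
#'
#' Standard step-up BH adjusted p-values (monotone, capped at 1), applied
#' across the `T - 1` intervals of a feature. A thin validating wrapper
#' over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    abort_argument("p-values must be numeric in [0, 1].")
  stats::p.adjust(p, method = "BH")
}
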