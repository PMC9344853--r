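#' Configuration for the synthetic-cohort generator
#'
#' The generator emulates an irregular two-group longitudinal study:
#' two groups of `n_subjects_per_group` subjects followed over
#' `[0, t_max]` days, per-subject timepoint counts drawn from a truncated
#' Poisson (`lambda_timepoints`, support >= `min_timepoints`), sampling
#' times concentrated early in the study with late-study dropout, AR(1)
#' within-subject noise with marginal variance `sigma`, and a
#' subject-level baseline offset. Five mean patterns are available: patterns 1-4 give
#' the signal group a triangular mean bump of height 50 over a 100-day
#' window starting at day `50 * pattern`; pattern 5 is a negative control
#' with no group difference.
#'
#' @param pattern integer 1-5.
#' @param sigma noise scale: the *variance* of the Normal noise around the
#'   pattern mean (the benchmark uses 1 and 5; default 5). The marginal
#'   noise SD is `sqrt(sigma)`.
#' @param n_subjects_per_group subjects per group (default 10).
#' @param rho AR(1) correlation between consecutive within-subject
#'   observations (default 0.4), `0 <= rho < 1`.
#' @param lambda_timepoints truncated-Poisson mean of the per-subject
#'   timepoint count (default 20).
#' @param t_max study length in days (default 500).
#' @param n_features number of features to simulate (default 1000).
#' @param seed integer seed; the same config reproduces the cohort exactly.
#' @param dropout with `TRUE` (default), sampling times follow a linearly
#'   decreasing (triangular) density on `[0, t_max]` and each subject's
#'   series is additionally truncated at a dropout time drawn uniformly on
#'   `[0.6 t_max, t_max]`; with `FALSE`, times are uniform and complete.
#' @param min_timepoints lower truncation of the Poisson count (default 3).
#' @param baseline_sd SD of the per-subject baseline offset (default
#'   `sqrt(sigma) / 2`, half the noise SD); a level shift that baseline
#'   adjustment is meant to absorb, without changing the ground truth.
#' @param gap_aware if `TRUE`, AR(1) correlation decays with the time gap
#'   (`rho^dt`); default `FALSE` (consecutive-observation indexing).
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(pattern, sigma = 5, n_subjects_per_group = 10,
                              rho = 0.4, lambda_timepoints = 20,
                              t_max = 500, n_features = 1000, seed = 1,
                              dropout = TRUE, min_timepoints = 3,
                              baseline_sd = sqrt(sigma) / 2,
                              gap_aware = FALSE) {
  if (!pattern %in% 1:5) abort_argument("`pattern` must be an integer in 1..5.")
  if (!is_scalar_number(sigma) || sigma <= 0) abort_argument("`sigma` must be > 0.")
  if (n_subjects_per_group < 2) abort_argument("need >= 2 subjects per group.")
  if (!is_scalar_number(rho) || rho < 0 || rho >= 1)
    abort_argument("`rho` must satisfy 0 <= rho < 1.")
  if (lambda_timepoints <= 0 || t_max <= 0 || n_features < 1)
    abort_argument("counts and scales must be positive.")
  if (min_timepoints < 2) abort_argument("`min_timepoints` must be >= 2.")
  structure(list(pattern = as.integer(pattern), sigma = sigma,
                 n_subjects_per_group = as.integer(n_subjects_per_group),
                 rho = rho, lambda_timepoints = lambda_timepoints,
                 t_max = t_max, n_features = as.integer(n_features),
                 seed = as.integer(seed), dropout = isTRUE(dropout),
                 min_timepoints = as.integer(min_timepoints),
                 baseline_sd = baseline_sd, gap_aware = isTRUE(gap_aware)),
            class = "simulation_config")
}

# Truly-different window [lo, hi] for a pattern; NULL for pattern 5.
pattern_window <- function(pattern) {
  if (pattern %in% 1:4) c(50 * pattern, 50 * pattern + 100) else NULL
}

#' Mean trajectory of a simulated pattern
#'
#' Deterministic mean at time `t`: the reference group sits at 10
#' throughout; the signal group of pattern `p` in 1-4 adds a triangular
#' bump rising from 0 to 50 over `(50p, 50p + 50]` and falling back over
#' `(50p + 50, 50p + 100]`. Pattern 5 has no bump for either group. Noise
#' (AR(1) with marginal SD `sigma`) is added around this mean by the
#' subject-series generator, so the marginal distribution at any time is
#' Normal(mean, sigma).
#'
#' @param pattern integer 1-5.
#' @param group `"signal"` or `"reference"`.
#' @param t numeric vector of times in `[0, t_max]`.
#' @return numeric vector of means.
#' @examples
#' pattern_mean(1, "signal", 100)    # apex: 60
#' pattern_mean(5, "signal", 100)    # 10
#' pattern_mean(3, "signal", 100)    # outside its window: 10
#' @export
pattern_mean <- function(pattern, group = c("signal", "reference"), t) {
  group <- match.arg(group)
  base <- rep(10, length(t))
  if (group == "reference" || pattern == 5L) return(base)
  w <- pattern_window(pattern)
  lo <- w[1]; mid <- w[1] + 50; hi <- w[2]
  bump <- ifelse(t > lo & t <= mid, t - lo,
                 ifelse(t > mid & t <= hi, hi - t, 0))
  base + bump
}

# Truncated Poisson draw with support >= min.
rtpois <- function(n, lambda, min) {
  out <- integer(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rpois(length(need), lambda)
    ok <- draw >= min
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Stationary AR(1) noise with marginal SD sigma along ordered times.
ar1_noise <- function(times, rho, sigma, gap_aware = FALSE) {
  n <- length(times)
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sigma)
  if (n > 1) {
    for (j in 2:n) {
      r <- if (gap_aware) rho^abs(times[j] - times[j - 1]) else rho
      e[j] <- r * e[j - 1] + rnorm(1, 0, sigma * sqrt(1 - r^2))
    }
  }
  e
}

# Sampling-time design for one subject (shared across features).
draw_subject_times <- function(config) {
  n_t <- rtpois(1, config$lambda_timepoints, config$min_timepoints)
  u <- runif(n_t)
  times <- if (config$dropout) {
    config$t_max * (1 - sqrt(1 - u))  # triangular density, mode at 0
  } else {
    config$t_max * u
  }
  times <- sort(times)
  if (config$dropout) {
    cutoff <- runif(1, 0.6 * config$t_max, config$t_max)
    keep <- times <= cutoff
    keep[seq_len(min(config$min_timepoints, length(times)))] <- TRUE
    times <- times[keep]
  }
  times
}

#' Simulate one subject's series under a pattern
#'
#' Draws the subject's sampling design (truncated-Poisson number of
#' timepoints, non-uniform times with optional dropout) and measurement
#' values: the pattern mean plus stationary AR(1) noise with marginal
#' variance `sigma`. Operates on the current RNG state; wrap in
#' [withr::with_seed()] for standalone reproducibility.
#'
#' @param config a [simulation_config()].
#' @param group `"signal"` or `"reference"`.
#' @return list with `times` (sorted) and `values`.
#' @export
simulate_subject_series <- function(config, group = c("signal", "reference")) {
  group <- match.arg(group)
  times <- draw_subject_times(config)
  mu <- pattern_mean(config$pattern, group, times)
  noise <- ar1_noise(times, config$rho, sqrt(config$sigma), config$gap_aware)
  list(times = times, values = mu + noise)
}

#' Simulate a two-group longitudinal cohort with ground truth
#'
#' Generates `n_features` independent features on a shared sampling
#' design: the subjects and their sample times are drawn once (features
#' are measured on the same physical samples), while the noise and a
#' per-subject baseline offset are drawn fresh per feature. For patterns
#' 1-4 the group labelled `"case"` carries the signal bump; pattern 5 has
#' no difference. The truly-different unit intervals are attached per
#' feature.
#'
#' @param config a [simulation_config()].
#' @return object of class `simulated_cohort`: list with `dataset` (a
#'   [longitudinal_dataset()]), `truth` (tibble of truly-different unit
#'   intervals per feature: `feature_id`, `t_start`, `t_end`; empty for
#'   pattern 5), `window` (the `[lo, hi]` bump window or `NULL`), and
#'   `config`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(pattern = 1, n_features = 2,
#'                                             seed = 42))
#' cohort$window  # c(50, 150)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    abort_argument("`config` must come from simulation_config().")
  n <- config$n_subjects_per_group
  subjects <- sprintf("S%02d", seq_len(2 * n))
  groups <- rep(c("case", "control"), each = n)
  roles <- ifelse(groups == "case", "signal", "reference")

  withr::with_seed(config$seed, {
    design <- lapply(seq_along(subjects), function(i) draw_subject_times(config))
    md <- do.call(rbind, lapply(seq_along(subjects), function(i) {
      tt <- design[[i]]
      data.frame(sample_id = sprintf("%s_t%02d", subjects[i], seq_along(tt)),
                 subject_id = subjects[i], group = groups[i], time = tt)
    }))
    n_samples <- nrow(md)
    feature_ids <- sprintf("feat_%04d", seq_len(config$n_features))
    values <- matrix(NA_real_, config$n_features, n_samples,
                     dimnames = list(feature_ids, md$sample_id))
    col_of <- split(seq_len(n_samples), md$subject_id)
    for (f in seq_len(config$n_features)) {
      for (i in seq_along(subjects)) {
        tt <- design[[i]]
        mu <- pattern_mean(config$pattern, roles[i], tt)
        offset <- rnorm(1, 0, config$baseline_sd)
        noise <- ar1_noise(tt, config$rho, sqrt(config$sigma), config$gap_aware)
        values[f, col_of[[subjects[i]]]] <- mu + offset + noise
      }
    }
  })

  w <- pattern_window(config$pattern)
  truth <- if (is.null(w)) {
    tibble::tibble(feature_id = character(), t_start = numeric(),
                   t_end = numeric())
  } else {
    starts <- seq(w[1], w[2] - 1)
    tibble::tibble(
      feature_id = rep(rownames(values), each = length(starts)),
      t_start = rep(starts, config$n_features),
      t_end = rep(starts + 1, config$n_features))
  }

  structure(list(dataset = longitudinal_dataset(values, md),
                 truth = truth, window = w, config = config),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> pattern %d, sigma=%g, %d features\n",
              x$config$pattern, x$config$sigma, x$config$n_features))
  if (is.null(x$window)) {
    cat("  negative control: no truly different intervals\n")
  } else {
    cat(sprintf("  truly different window: [%g, %g] days\n",
                x$window[1], x$window[2]))
  }
  print(x$dataset)
  invisible(x)
}

#' Write a simulated cohort to delimited files
#'
#' Emits the standard analysis inputs plus the ground truth:
#' `features.csv` (feature table), `metadata.csv`, and `truth.csv`
#' (`feature_id`, `t_start`, `t_end`, `truly_different` over the unit grid
#' on `[0, t_max]`).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "simulated_cohort"))
    abort_argument("`cohort` must come from simulate_cohort().")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- cohort$dataset
  ft <- tibble::as_tibble(cbind(data.frame(feature_id = rownames(ds$values)),
                                as.data.frame(ds$values)))
  paths <- file.path(dir, c("features.csv", "metadata.csv", "truth.csv"))
  readr::write_csv(ft, paths[1])
  readr::write_csv(ds$metadata, paths[2])
  t_max <- cohort$config$t_max
  starts <- seq(0, t_max - 1)
  w <- cohort$window
  truly <- if (is.null(w)) rep(FALSE, length(starts)) else {
    starts >= w[1] & (starts + 1) <= w[2]
  }
  truth_long <- tibble::tibble(
    feature_id = rep(rownames(ds$values), each = length(starts)),
    t_start = rep(starts, nrow(ds$values)),
    t_end = rep(starts + 1, nrow(ds$values)),
    truly_different = rep(truly, nrow(ds$values)))
  readr::write_csv(truth_long, paths[3])
  invisible(paths)
}
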