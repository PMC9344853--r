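test_that("the interval statistic matches hand arithmetic and its sign convention", {
  g <- time_grid(c(0, 1))
  f1 <- list(eta_hat = c(3, 5), se = c(1, 1), grid = g)
  f2 <- list(eta_hat = c(1, 1), se = c(1, 1), grid = g)
  expect_equal(interval_statistics(f1, f2), 3 / sqrt(2))
  # antisymmetry under swapping the groups
  expect_equal(interval_statistics(f2, f1), -3 / sqrt(2))
  # identical curves give exact zeros
  expect_identical(interval_statistics(f1, f1), 0)
  # grid mismatch is an argument error
  f3 <- list(eta_hat = c(1, 1), se = c(1, 1), grid = time_grid(c(0, 2)))
  expect_error(interval_statistics(f1, f3), class = "lontide_argument_error")
  # multi-interval case, computed by hand from the trapezoid formula
  g4 <- time_grid(0:3)
  fa <- list(eta_hat = c(0, 2, 4, 0), se = rep(2, 4), grid = g4)
  fb <- list(eta_hat = c(0, 0, 0, 0), se = rep(1, 4), grid = g4)
  manual <- c(1, 3, 2) / sqrt(2^2 + 1^2)
  expect_equal(interval_statistics(fa, fb), manual)
})

test_that("subject-level permutation is uniform over label arrangements", {
  subjects <- data.frame(subject_id = c("a", "b", "c", "d"),
                         group = c("1", "1", "2", "2"))
  maps <- vapply(1:400, function(s) {
    paste(permute_group_labels(subjects, s), collapse = "")
  }, "")
  # exactly choose(4, 2) = 6 distinct assignments occur
  expect_equal(length(unique(maps)), 6L)
  # group sizes always preserved
  expect_true(all(vapply(1:50, function(s) {
    sum(permute_group_labels(subjects, s) == "1") == 2L
  }, TRUE)))
  expect_error(permute_group_labels(
    data.frame(subject_id = c("a", "b", "c"), group = c("1", "2", "2")), 1),
    class = "lontide_design_error")
})

test_that("empirical p-values enumerate the pooled indicator sums", {
  pool <- c(-1, 0, 1)
  expect_equal(empirical_pvalues(2, pool), 0)
  expect_equal(empirical_pvalues(0.5, pool), 1 / 3)
  expect_equal(empirical_pvalues(-2, pool), 0)
  expect_equal(empirical_pvalues(-0.5, pool), 1 / 3)
  expect_equal(empirical_pvalues(0, pool), 1)      # zero statistic -> p = 1
  # strict inequalities: a tie does not count
  expect_equal(empirical_pvalues(1, pool), 0)
  expect_equal(empirical_pvalues(c(2, 0.5, -2), pool), c(0, 1/3, 0))
  # cross-check against direct counting on random pools
  withr::with_seed(14, {
    pool <- rnorm(500)
    obs <- rnorm(20)
    manual <- vapply(obs, function(s) {
      if (s > 0) sum(pool > s) / 500
      else if (s < 0) sum(pool < s) / 500
      else 1
    }, 0)
    expect_equal(empirical_pvalues(obs, pool), manual)
  })
})

test_that("BH adjustment matches the hand-computed step-up and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "lontide_argument_error")
  withr::with_seed(15, {
    p <- runif(30)
    expect_true(all(bh_adjust(p) >= p))
  })
})

test_that("the permutation null honors its length contract and seed determinism", {
  ds <- make_tiny_dataset(n_time = 6)
  md <- ds$metadata
  y <- ds$values[1, ]
  grid <- lontide:::default_time_grid(md, ds$group_levels, step = 20)
  nul <- build_null(md$time, y, md$subject_id, md$group, grid, B = 5,
                    rng_seed = 3)
  expect_equal(length(nul$values), 5L * grid$n_intervals)
  expect_true(all(is.finite(nul$values)))
  nul2 <- build_null(md$time, y, md$subject_id, md$group, grid, B = 5,
                     rng_seed = 3)
  expect_identical(nul$values, nul2$values)
  nul3 <- build_null(md$time, y, md$subject_id, md$group, grid, B = 5,
                     rng_seed = 4)
  expect_false(identical(nul$values, nul3$values))
})

test_that("sampled permutation p-values converge to the exhaustive enumeration", {
  # 2+2 subjects: only choose(4,2) = 6 label assignments exist
  ds <- make_tiny_dataset(n_time = 8, seed = 19)
  md <- ds$metadata
  y <- ds$values[1, ]
  grid <- lontide:::default_time_grid(md, ds$group_levels, step = 15)
  eng <- lontide:::spline_engine(md$time, y, md$subject_id, grid$points, k = 10)
  subjects <- unique(md$subject_id)
  # exhaustive oracle: every way to pick 2 subjects as group 1
  combos <- combn(subjects, 2, simplify = FALSE)
  ex_pool <- unlist(lapply(combos, function(s1) {
    s2 <- setdiff(subjects, s1)
    f1 <- lontide:::fit_subset(eng, s1)
    f2 <- lontide:::fit_subset(eng, s2)
    lontide:::stat_from_curves(f1$eta, f1$se, f2$eta, f2$se)
  }))
  obs_f1 <- lontide:::fit_subset(eng, subjects[1:2])
  obs_f2 <- lontide:::fit_subset(eng, subjects[3:4])
  obs <- lontide:::stat_from_curves(obs_f1$eta, obs_f1$se,
                                    obs_f2$eta, obs_f2$se)
  p_ex <- empirical_pvalues(obs, ex_pool)
  nul <- build_null(md$time, y, md$subject_id, md$group, grid, B = 600,
                    rng_seed = 5, k = 10)
  p_mc <- empirical_pvalues(obs, nul)
  expect_lt(max(abs(p_mc - p_ex)), 0.08)  # Monte-Carlo error at B = 600
})

test_that("relabeling the groups negates statistics and preserves p-values", {
  coh <- make_small_cohort(pattern = 1, n_features = 1, seed = 31,
                           n_subjects_per_group = 3, lambda_timepoints = 8)
  ds <- coh$dataset
  ds_swapped <- longitudinal_dataset(ds$values, ds$metadata,
                                     reference_group = "control")
  r1 <- analyze_feature(ds, "feat_0001", adjust = "none", B = 40, seed = 9)
  r2 <- analyze_feature(ds_swapped, "feat_0001", adjust = "none", B = 40,
                        seed = 9)
  expect_equal(r2$intervals$statistic, -r1$intervals$statistic)
  expect_equal(r2$intervals$p_value, r1$intervals$p_value)
  expect_equal(r2$intervals$significant, r1$intervals$significant)
  # the substantive winner is unchanged by relabeling which group is "group 1"
  expect_equal(r2$intervals$dominant_group, r1$intervals$dominant_group)
})

test_that("p-values are scale invariant through either adjustment", {
  coh <- make_small_cohort(pattern = 2, n_features = 1, seed = 33,
                           n_subjects_per_group = 3, lambda_timepoints = 8)
  ds <- coh$dataset
  ds_scaled <- longitudinal_dataset(ds$values * 37.5, ds$metadata)
  for (adj in c("min_max", "none")) {
    r1 <- analyze_feature(ds, "feat_0001", adjust = adj, B = 30, seed = 2)
    r2 <- analyze_feature(ds_scaled, "feat_0001", adjust = adj, B = 30,
                          seed = 2)
    expect_equal(r1$intervals$p_value, r2$intervals$p_value,
                 tolerance = 1e-12)
  }
  # log-ratio: positive rescaling leaves the adjusted data untouched
  r1 <- analyze_feature(ds, "feat_0001", adjust = "log_ratio", B = 30,
                        seed = 2)
  r2 <- analyze_feature(ds_scaled, "feat_0001", adjust = "log_ratio", B = 30,
                        seed = 2)
  expect_equal(r1$intervals$p_value, r2$intervals$p_value)
})

test_that("feature analysis is reproducible and its intervals tile the grid", {
  coh <- make_small_cohort(pattern = 1, n_features = 2, seed = 35,
                           n_subjects_per_group = 3, lambda_timepoints = 8)
  r1 <- analyze_feature(coh$dataset, "feat_0001", B = 25, seed = 11)
  r2 <- analyze_feature(coh$dataset, "feat_0001", B = 25, seed = 11)
  expect_identical(r1$intervals, r2$intervals)
  expect_equal(r1$intervals$t_start[-1],
               r1$intervals$t_end[-nrow(r1$intervals)])
  expect_true(all(r1$intervals$p_value >= 0 & r1$intervals$p_value <= 1))
  expect_true(all(r1$intervals$p_adjusted >= r1$intervals$p_value - 1e-15))
  expect_identical(r1$intervals$significant,
                   r1$intervals$p_adjusted < r1$alpha)
})

test_that("batch analysis skips failing features without aborting and supports global BH", {
  coh <- make_small_cohort(pattern = 5, n_features = 3, seed = 37,
                           n_subjects_per_group = 3, lambda_timepoints = 8)
  ds <- coh$dataset
  # poison feature 2 so log-ratio drops too many subjects in one group
  bad <- ds$metadata$group == "case"
  vals <- ds$values
  vals[2, bad] <- -abs(vals[2, bad])
  ds2 <- longitudinal_dataset(vals, ds$metadata)
  res <- analyze_dataset(ds2, adjust = "log_ratio", B = 20, seed = 13)
  expect_equal(res$skipped$feature_id, "feat_0002")
  expect_setequal(unique(res$results$feature_id),
                  c("feat_0001", "feat_0003"))
  # global BH adjusts across features x intervals jointly
  resg <- analyze_dataset(ds2, adjust = "log_ratio", B = 20, seed = 13,
                          bh_scope = "global")
  expect_equal(resg$results$p_adjusted, bh_adjust(resg$results$p_value))
})
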