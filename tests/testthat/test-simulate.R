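test_that("pattern means follow the shifted triangular bump", {
  # apex of pattern 1 at day 100: 10 + 50
  expect_equal(pattern_mean(1, "signal", 100), 60)
  expect_equal(pattern_mean(5, "signal", 100), 10)
  expect_equal(pattern_mean(5, "reference", 321), 10)
  # pattern 3's bump lives on (150, 250]; day 100 is outside it
  expect_equal(pattern_mean(3, "signal", 100), 10)
  # shift rule: pattern p rises on (50p, 50p+50], falls on (50p+50, 50p+100]
  for (p in 1:4) {
    lo <- 50 * p
    expect_equal(pattern_mean(p, "signal", lo), 10)        # left edge open
    expect_equal(pattern_mean(p, "signal", lo + 25), 35)
    expect_equal(pattern_mean(p, "signal", lo + 50), 60)
    expect_equal(pattern_mean(p, "signal", lo + 75), 35)
    expect_equal(pattern_mean(p, "signal", lo + 100), 10)  # right edge closed
    expect_equal(pattern_mean(p, "reference", lo + 50), 10)
  }
})

test_that("per-subject timepoint counts follow the truncated Poisson(20)", {
  n <- withr::with_seed(101, lontide:::rtpois(10000, 20, 3))
  expect_true(all(n >= 3))
  expect_lt(abs(mean(n) - 20) / 20, 0.02)
})

test_that("AR(1) noise has the configured marginal scale and lag-1 correlation", {
  acf1 <- function(rho, sd = 1, n = 40, reps = 400, seed = 103) {
    withr::with_seed(seed, {
      pairs <- do.call(rbind, lapply(seq_len(reps), function(i) {
        e <- lontide:::ar1_noise(seq_len(n), rho, sd)
        cbind(e[-n], e[-1])
      }))
    })
    c(cor(pairs[, 1], pairs[, 2]), sd(pairs))
  }
  out <- acf1(0.4, sd = sqrt(5))
  expect_lt(abs(out[1] - 0.4), 0.03)
  expect_lt(abs(out[2] - sqrt(5)) / sqrt(5), 0.03)
  # degenerate AR(1): rho = 0 gives (near) independent noise
  expect_lt(abs(acf1(0, seed = 104)[1]), 0.03)
})

test_that("reference-group values have marginal mean 10 and variance sigma", {
  cfg <- simulation_config(pattern = 5, sigma = 5, n_features = 1, seed = 1)
  vals <- withr::with_seed(105, {
    unlist(lapply(1:300, function(i) {
      simulate_subject_series(cfg, "reference")$values
    }))
  })
  expect_lt(abs(mean(vals) - 10), 0.1)
  expect_lt(abs(sd(vals) - sqrt(5)) / sqrt(5), 0.05)
})

test_that("dropout concentrates samples in the first half of the study", {
  cfg <- simulation_config(pattern = 1, n_features = 1, seed = 9,
                           dropout = TRUE)
  tt <- withr::with_seed(106, {
    unlist(lapply(1:200, function(i) lontide:::draw_subject_times(cfg)))
  })
  expect_gt(sum(tt < 250), 2 * sum(tt >= 250))
  expect_true(all(tt >= 0 & tt <= 500))
})

test_that("cohorts carry the pattern's ground-truth window", {
  coh1 <- make_small_cohort(pattern = 1, n_features = 3, seed = 11)
  expect_equal(coh1$window, c(50, 150))
  expect_equal(sort(unique(coh1$truth$t_start)), 50:149)
  expect_true(all(coh1$truth$t_end == coh1$truth$t_start + 1))
  expect_setequal(unique(coh1$truth$feature_id), coh1$dataset$features)
  coh5 <- make_small_cohort(pattern = 5, n_features = 3, seed = 11)
  expect_null(coh5$window)
  expect_equal(nrow(coh5$truth), 0L)
})

test_that("simulated cohorts are valid datasets for any seed and reproducible", {
  for (seed in c(2, 23, 444)) {
    coh <- make_small_cohort(pattern = 3, n_features = 2, seed = seed)
    expect_s3_class(coh$dataset, "longitudinal_dataset")  # constructor validates
    expect_equal(coh$dataset$group_levels, c("case", "control"))
  }
  c1 <- make_small_cohort(pattern = 2, n_features = 2, seed = 77)
  c2 <- make_small_cohort(pattern = 2, n_features = 2, seed = 77)
  expect_identical(c1$dataset$values, c2$dataset$values)
  expect_identical(c1$dataset$metadata, c2$dataset$metadata)
  c3 <- make_small_cohort(pattern = 2, n_features = 2, seed = 78)
  expect_false(identical(c1$dataset$values, c3$dataset$values))
})

test_that("cohort files round-trip through the writer", {
  coh <- make_small_cohort(pattern = 1, n_features = 2, seed = 13,
                           n_subjects_per_group = 2, lambda_timepoints = 5)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir, c("features.csv",
                                               "metadata.csv",
                                               "truth.csv")))))
  ds <- load_dataset(file.path(dir, "features.csv"),
                     file.path(dir, "metadata.csv"))
  expect_equal(ds$values, coh$dataset$values, tolerance = 1e-12)
  truth <- readr::read_csv(file.path(dir, "truth.csv"),
                           show_col_types = FALSE)
  expect_equal(sum(truth$truly_different) / length(unique(truth$feature_id)),
               100)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(pattern = 6), class = "lontide_argument_error")
  expect_error(simulation_config(1, sigma = -1), class = "lontide_argument_error")
  expect_error(simulation_config(1, rho = 1), class = "lontide_argument_error")
  expect_error(simulation_config(1, n_subjects_per_group = 1),
               class = "lontide_argument_error")
})
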