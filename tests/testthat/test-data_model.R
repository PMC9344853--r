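test_that("a well-formed dataset is assembled and aligned by sample_id", {
  raw <- make_raw_tables()
  # shuffle metadata rows: alignment must come from sample_id, not position
  md <- raw$metadata[sample(nrow(raw$metadata)), ]
  ds <- longitudinal_dataset(raw$values, md)
  expect_s3_class(ds, "longitudinal_dataset")
  expect_equal(dim(ds$values), c(3L, 8L))
  expect_equal(ds$metadata$sample_id, colnames(ds$values))
  expect_equal(ds$group_levels, c("g1", "g2"))
  # explicit reference group flips the level order
  ds2 <- longitudinal_dataset(raw$values, md, reference_group = "g2")
  expect_equal(ds2$group_levels, c("g2", "g1"))
})

test_that("design and format violations are rejected with typed errors", {
  raw <- make_raw_tables()
  # subject in both groups
  md <- raw$metadata
  md$group[md$subject_id == "A"] <- c("g1", "g2")
  expect_error(longitudinal_dataset(raw$values, md),
               class = "lontide_design_error")
  # < 2 subjects in one group
  md <- raw$metadata
  md$group <- c(rep("g1", 6), rep("g2", 2))
  md$subject_id <- rep(c("A", "B", "C", "D"), each = 2)
  expect_error(longitudinal_dataset(raw$values, md),
               class = "lontide_design_error")
  # duplicate (subject, time)
  md <- raw$metadata
  md$time[2] <- md$time[1]
  expect_error(longitudinal_dataset(raw$values, md),
               class = "lontide_design_error")
  # missing column
  expect_error(longitudinal_dataset(raw$values, raw$metadata[, -4]),
               class = "lontide_format_error")
  # sample id mismatch
  vals <- raw$values
  colnames(vals)[1] <- "not_in_metadata"
  expect_error(longitudinal_dataset(vals, raw$metadata),
               class = "lontide_format_error")
  # non-finite measurement must be NA, not Inf
  vals <- raw$values
  vals[1, 1] <- Inf
  expect_error(longitudinal_dataset(vals, raw$metadata),
               class = "lontide_format_error")
})

test_that("validation accepts randomized well-formed tables and rejects corrupted ones", {
  corruptions <- list(
    function(md) { md$group[md$subject_id == md$subject_id[1]] <-
      c("g1", "g2"); md },
    function(md) { md$time[1] <- NA_real_; md },
    function(md) { md$sample_id[2] <- md$sample_id[1]; md },
    function(md) { names(md)[3] <- "cohort"; md })
  for (seed in 1:5) {
    raw <- make_raw_tables(seed)
    expect_silent(longitudinal_dataset(raw$values, raw$metadata))
    for (corrupt in corruptions) {
      expect_error(longitudinal_dataset(raw$values, corrupt(raw$metadata)),
                   class = "lontide_error")
    }
  }
})

test_that("load_dataset round-trips delimited files and reports bad input", {
  raw <- make_raw_tables()
  dir <- withr::local_tempdir()
  fpath <- file.path(dir, "features.csv")
  mpath <- file.path(dir, "metadata.csv")
  ft <- cbind(data.frame(feature_id = rownames(raw$values)),
              as.data.frame(raw$values))
  readr::write_csv(ft, fpath)
  readr::write_csv(raw$metadata, mpath)
  ds <- load_dataset(fpath, mpath)
  expect_equal(unname(ds$values), unname(raw$values))
  expect_equal(ds$features, rownames(raw$values))

  # tab-delimited variant
  fpath2 <- file.path(dir, "features.tsv")
  readr::write_tsv(ft, fpath2)
  ds2 <- load_dataset(fpath2, mpath)
  expect_equal(ds2$values, ds$values)

  # metadata missing the time column -> format error naming it
  md_bad <- raw$metadata[, c("sample_id", "subject_id", "group")]
  mpath_bad <- file.path(dir, "md_bad.csv")
  readr::write_csv(md_bad, mpath_bad)
  expect_error(load_dataset(fpath, mpath_bad), "time",
               class = "lontide_format_error")
})

test_that("write_results/read_results is the identity on all typed fields", {
  res <- tibble::tibble(
    feature_id = rep("f1", 3),
    t_start = c(0, 1, 2), t_end = c(1, 2, 3),
    statistic = c(1.234567891, -2.5, 0),
    p_value = c(0.001, 0.5, 1), p_adjusted = c(0.003, 0.75, 1),
    significant = c(TRUE, FALSE, FALSE),
    dominant_group = c("case", "control", "none"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path)
  back <- read_results(path)
  expect_equal(as.data.frame(back), as.data.frame(res))
  expect_error(write_results(res[0, ], path), class = "lontide_argument_error")
  expect_error(write_results(res[, -3], path), class = "lontide_format_error")
})

test_that("time grids enforce monotone points and no-overlap defaults", {
  g <- time_grid(c(0, 1, 2.5, 4))
  expect_equal(g$n_intervals, 3L)
  expect_equal(g$t_start, c(0, 1, 2.5))
  expect_error(time_grid(c(1, 1, 2)), class = "lontide_argument_error")
  expect_error(time_grid(5), class = "lontide_argument_error")
  md <- data.frame(time = c(0, 10, 2, 8), group = c("a", "a", "b", "b"))
  dg <- lontide:::default_time_grid(md, c("a", "b"))
  expect_gte(min(dg$points), 2)
  expect_lte(max(dg$points), 8)
})
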