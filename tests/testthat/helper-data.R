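# Shared fixture builders (everything is generated in code).

# A minimal well-formed dataset: 2 subjects per group, `n_time` timepoints
# each, linear-ish values.
make_tiny_dataset <- function(n_time = 5, n_subj_per_group = 2, seed = 42,
                              groups = c("case", "control")) {
  withr::with_seed(seed, {
    subjects <- sprintf("S%02d", seq_len(2 * n_subj_per_group))
    grp <- rep(groups, each = n_subj_per_group)
    md <- do.call(rbind, lapply(seq_along(subjects), function(i) {
      tt <- sort(runif(n_time, 0, 100))
      data.frame(sample_id = paste0(subjects[i], "_", seq_len(n_time)),
                 subject_id = subjects[i], group = grp[i], time = tt)
    }))
    vals <- matrix(rnorm(3 * nrow(md), mean = 10, sd = 1), nrow = 3,
                   dimnames = list(paste0("f", 1:3), md$sample_id))
    longitudinal_dataset(vals, md)
  })
}

# A small simulated cohort for end-to-end tests.
make_small_cohort <- function(pattern = 1, n_features = 2, seed = 7, ...) {
  simulate_cohort(simulation_config(pattern = pattern,
                                    n_features = n_features, seed = seed,
                                    ...))
}

# Raw metadata/feature tables (pre-validation), for corruption tests.
make_raw_tables <- function(seed = 1) {
  withr::with_seed(seed, {
    md <- data.frame(
      sample_id = paste0("s", 1:8),
      subject_id = rep(c("A", "B", "C", "D"), each = 2),
      group = rep(c("g1", "g2"), each = 4),
      time = rep(c(0, 10), 4))
    vals <- matrix(rnorm(24, 10), nrow = 3,
                   dimnames = list(paste0("f", 1:3), md$sample_id))
    list(values = vals, metadata = md)
  })
}
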