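#' Assemble and validate a longitudinal omics dataset
#'
#' Bundles an `m x n` feature quantification matrix with per-sample metadata
#' (subject, group, collection time) into the container all other functions
#' consume. Columns of `values` and rows of `metadata` are aligned by
#' `sample_id`, never by position.
#'
#' The design is unpaired: every subject belongs to exactly one of two
#' groups. Group labels may be arbitrary strings; they are mapped to
#' group 1 / group 2 by sorted order unless `reference_group` names the
#' label to treat as group 1 (the sign convention of the interval statistic
#' is group 1 minus group 2).
#'
#' @param values numeric matrix, features in rows (rownames = feature IDs),
#'   samples in columns (colnames = sample IDs). `NA` marks a missing
#'   measurement; missing entries are dropped per feature downstream, never
#'   imputed.
#' @param metadata data frame with columns `sample_id`, `subject_id`,
#'   `group`, `time` (numeric, continuous study time, e.g. days).
#' @param reference_group optional group label to use as group 1.
#' @return An object of class `longitudinal_dataset`: a list with elements
#'   `values`, `metadata` (tibble, ordered as the matrix columns),
#'   `features`, and `group_levels` (length 2, group 1 first).
#' @examples
#' md <- tibble::tibble(
#'   sample_id = paste0("s", 1:8),
#'   subject_id = rep(c("A", "B", "C", "D"), each = 2),
#'   group = rep(c("case", "control"), each = 4),
#'   time = rep(c(0, 10), 4))
#' vals <- matrix(rnorm(16, 10), 2, 8,
#'                dimnames = list(c("f1", "f2"), md$sample_id))
#' ds <- longitudinal_dataset(vals, md)
#' ds
#' @export
longitudinal_dataset <- function(values, metadata, reference_group = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_format("`values` must be a numeric matrix (features x samples).")
  if (is.null(rownames(values)))
    abort_format("`values` must have rownames giving feature IDs.")
  if (is.null(colnames(values)))
    abort_format("`values` must have colnames giving sample IDs.")
  metadata <- validate_metadata(metadata)

  mat_ids <- colnames(values)
  if (!setequal(mat_ids, metadata$sample_id)) {
    missing_md <- setdiff(mat_ids, metadata$sample_id)
    missing_mat <- setdiff(metadata$sample_id, mat_ids)
    abort_format(paste0(
      "feature table and metadata sample IDs disagree",
      if (length(missing_md)) paste0("; absent from metadata: ",
                                     paste(head(missing_md, 5), collapse = ", ")),
      if (length(missing_mat)) paste0("; absent from feature table: ",
                                      paste(head(missing_mat, 5), collapse = ", "))))
  }
  metadata <- metadata[match(mat_ids, metadata$sample_id), , drop = FALSE]

  if (any(is.infinite(values)))
    abort_format("`values` contains non-finite (infinite) measurements; use NA for missing.")
  if (anyDuplicated(rownames(values)))
    abort_format("duplicated feature IDs in `values` rownames.")

  groups <- sort(unique(as.character(metadata$group)))
  if (length(groups) != 2L)
    abort_design(sprintf("exactly 2 groups are required, found %d (%s).",
                         length(groups), paste(head(groups, 5), collapse = ", ")))
  if (!is.null(reference_group)) {
    if (!reference_group %in% groups)
      abort_argument(sprintf("reference_group '%s' is not a group label.", reference_group))
    groups <- c(reference_group, setdiff(groups, reference_group))
  }

  # per-group subject counts and per-subject timepoint counts
  subj_group <- unique(metadata[, c("subject_id", "group")])
  n_subj <- table(factor(subj_group$group, levels = groups))
  if (any(n_subj < 2L))
    abort_design(sprintf("each group needs >= 2 subjects; group '%s' has %d.",
                         names(n_subj)[which.min(n_subj)], min(n_subj)))
  n_tp <- table(metadata$subject_id)
  if (any(n_tp < 2L))
    abort_design(sprintf("every subject needs >= 2 timepoints; subject '%s' has %d.",
                         names(n_tp)[which.min(n_tp)], min(n_tp)))

  structure(list(values = values,
                 metadata = tibble::as_tibble(metadata),
                 features = rownames(values),
                 group_levels = groups),
            class = "longitudinal_dataset")
}

validate_metadata <- function(metadata) {
  if (!is.data.frame(metadata))
    abort_format("`metadata` must be a data frame.")
  required <- c("sample_id", "subject_id", "group", "time")
  missing <- setdiff(required, names(metadata))
  if (length(missing))
    abort_format(sprintf("metadata is missing required column(s): %s.",
                         paste(missing, collapse = ", ")))
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$subject_id <- as.character(metadata$subject_id)
  metadata$group <- as.character(metadata$group)
  if (!is.numeric(metadata$time))
    abort_format("metadata column `time` must be numeric.")
  if (any(!is.finite(metadata$time)))
    abort_format("metadata column `time` contains non-finite values.")
  if (anyDuplicated(metadata$sample_id))
    abort_format("metadata `sample_id` values must be unique.")
  dup_st <- duplicated(metadata[, c("subject_id", "time")])
  if (any(dup_st))
    abort_design(sprintf(
      "duplicate (subject_id, time) pairs (e.g. subject '%s' at t=%g); technical replicates are not supported.",
      metadata$subject_id[dup_st][1], metadata$time[dup_st][1]))
  multi <- tapply(metadata$group, metadata$subject_id,
                  function(g) length(unique(g)))
  if (any(multi > 1L))
    abort_design(sprintf("subject '%s' is assigned to more than one group (unpaired design required).",
                         names(multi)[multi > 1L][1]))
  metadata
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  n_subj <- table(unique(x$metadata[, c("subject_id", "group")])$group)[x$group_levels]
  cat(sprintf("<longitudinal_dataset> %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  groups: %s (%d subjects) vs %s (%d subjects)\n",
              x$group_levels[1], n_subj[1], x$group_levels[2], n_subj[2]))
  cat(sprintf("  time range: [%g, %g]\n",
              min(x$metadata$time), max(x$metadata$time)))
  invisible(x)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Load a feature table and sample metadata from delimited files
#'
#' Reads a feature quantification table (first column = feature ID, one
#' column per sample) and a sample metadata table (columns `sample_id`,
#' `subject_id`, `group`, `time`), aligns them by sample ID and returns a
#' validated [longitudinal_dataset()]. Comma- and tab-delimited files are
#' both accepted; the delimiter is sniffed from the extension
#' (`.tsv`/`.txt` = tab, anything else = comma).
#'
#' @param feature_table_path,metadata_path file paths.
#' @param reference_group optional group label to treat as group 1.
#' @return a `longitudinal_dataset`.
#' @export
load_dataset <- function(feature_table_path, metadata_path,
                         reference_group = NULL) {
  ft <- read_delim_auto(feature_table_path)
  md <- read_delim_auto(metadata_path)
  if (ncol(ft) < 2L)
    abort_format("feature table needs a feature-ID column plus >= 1 sample column.")
  feature_id <- as.character(ft[[1]])
  mat <- as.matrix(ft[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- feature_id
  longitudinal_dataset(mat, md, reference_group = reference_group)
}

#' Construct a grid of tested time intervals
#'
#' A time grid is a strictly increasing vector of `T` points defining the
#' `T - 1` contiguous intervals over which the interval statistic is
#' computed. The default grid used by the analysis functions is
#' equidistant with unit step over the time range shared by both groups
#' (no extrapolation beyond either group's observed range).
#'
#' @param points strictly increasing numeric vector, length >= 2.
#' @return object of class `time_grid`: list with `points`, `t_start`,
#'   `t_end` (the interval endpoints) and `n_intervals`.
#' @export
time_grid <- function(points) {
  points <- as.numeric(points)
  if (length(points) < 2L)
    abort_argument("a time grid needs at least 2 points.")
  if (any(!is.finite(points)) || any(diff(points) <= 0))
    abort_argument("time grid points must be finite and strictly increasing.")
  structure(list(points = points,
                 t_start = points[-length(points)],
                 t_end = points[-1],
                 n_intervals = length(points) - 1L),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d intervals over [%g, %g]\n",
              x$n_intervals, min(x$points), max(x$points)))
  invisible(x)
}

# Equidistant grid over the range covered by both groups of `metadata`
# (rows restricted to the samples actually in play).
default_time_grid <- function(metadata, group_levels, step = 1) {
  rng <- vapply(group_levels, function(g) {
    tt <- metadata$time[metadata$group == g]
    c(min(tt), max(tt))
  }, numeric(2))
  lo <- ceiling(max(rng[1, ]) / step) * step
  hi <- floor(min(rng[2, ]) / step) * step
  if (hi - lo < step)
    abort_design("the time ranges of the two groups do not overlap enough to form a grid.")
  time_grid(seq(lo, hi, by = step))
}

result_columns <- c("feature_id", "t_start", "t_end", "statistic",
                    "p_value", "p_adjusted", "significant", "dominant_group")

#' Write and read interval-result tables
#'
#' Results are stored long format, one row per (feature, interval), with
#' columns `feature_id, t_start, t_end, statistic, p_value, p_adjusted,
#' significant, dominant_group`. `read_results()` re-reads a written file
#' with identical values to full printed precision.
#'
#' @param results data frame of interval results (e.g. the `results`
#'   element of [analyze_dataset()]).
#' @param path output file; format sniffed from extension (default CSV).
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns a tibble.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    abort_argument("`results` must be a non-empty data frame; nothing written.")
  missing <- setdiff(result_columns, names(results))
  if (length(missing))
    abort_format(sprintf("results are missing column(s): %s.",
                         paste(missing, collapse = ", ")))
  out <- results[, result_columns]
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tryCatch(readr::write_delim(out, path, delim = delim),
           error = function(e) abort_io(sprintf("cannot write results to '%s': %s",
                                                path, conditionMessage(e))))
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  res <- read_delim_auto(path)
  missing <- setdiff(result_columns, names(res))
  if (length(missing))
    abort_format(sprintf("results file is missing column(s): %s.",
                         paste(missing, collapse = ", ")))
  res$dominant_group <- as.character(res$dominant_group)
  res
}
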