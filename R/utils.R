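# Internal helpers: condition constructors and seed derivation.

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = c("lontide_format_error", "lontide_error"), ...)
}

abort_design <- function(msg, ...) {
  rlang::abort(msg, class = c("lontide_design_error", "lontide_error"), ...)
}

abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = c("lontide_domain_error", "lontide_error"), ...)
}

abort_argument <- function(msg, ...) {
  rlang::abort(msg, class = c("lontide_argument_error", "lontide_error"), ...)
}

abort_fit <- function(msg, ...) {
  rlang::abort(msg, class = c("lontide_fit_error", "lontide_error"), ...)
}

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = c("lontide_io_error", "lontide_error"), ...)
}

# Deterministic child seed for feature `index` under a master seed, so batch
# results are independent of scheduling and feature order. Kept inside the
# 32-bit signed integer range required by set.seed().
child_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), is.numeric(index))
  mod <- 2147483587
  s <- (as.double(master_seed) %% mod) * 48271 + as.double(index) * 16807
  as.integer(s %% mod) + 1L
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
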