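# Internal helpers shared across modules.

# Abort unless `data` has all of `cols`.
assert_cols <- function(data, cols, fn) {
  if (!is.data.frame(data)) {
    cli::cli_abort("{.fn {fn}} expects a data frame, not {.cls {class(data)[1]}}.")
  }
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    cli::cli_abort("{.fn {fn}} requires column{?s} {.field {missing}}.")
  }
  invisible(data)
}

# Run `code` under a fixed RNG state when `seed` is given, untouched otherwise.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Deterministic small sub-seed stream derived from a base seed.
derive_seeds <- function(seed, n) {
  with_seed_opt(seed %||% 1L, sample.int(.Machine$integer.max - 1L, n))
}

# Coerce a two-column numeric object (matrix / data frame) to a plain matrix.
as_bivariate_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  if (!is.matrix(x) || ncol(x) != 2L || !is.numeric(x)) {
    cli::cli_abort("{.arg {arg}} must be a numeric matrix or data frame with 2 columns.")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    cli::cli_abort("{.arg {arg}} contains missing or non-finite values.")
  }
  unname(x)
}

# Duration-weighted overlap of frames [start, end] with a window [w0, w1].
frame_overlap <- function(start, end, w0, w1) {
  pmax(0, pmin(end, w1) - pmax(start, w0))
}
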